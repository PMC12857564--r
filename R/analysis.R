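#' Ensemble statistics for surface-hopping dynamics
#'
#' Population curves with binomial confidence bands, bootstrap standard
#' errors, exponential and delayed-exponential timescale fits, quantum
#' yields, photoproduct classifiers, hop-geometry tables, branching
#' ratios and interpolated reaction paths.
#'
#' @name analysis
NULL

#' Normal-approximation binomial confidence half-width
#'
#' dP = z * sqrt(p (1 - p) / n) with z the two-sided normal quantile
#' (1.959964 at 95%).
#'
#' @param p observed fraction in \[0, 1\].
#' @param n number of trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @return half-width of the interval.
#' @export
binomial_ci <- function(p, n, confidence = 0.95) {
  stop_if(any(n < 1), "n must be >= 1")
  stop_if(any(p < 0 | p > 1), "p must be in [0, 1]")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  z * sqrt(p * (1 - p) / n)
}

## active state of a trajectory at a set of times (carry last state
## forward past early termination)
active_at <- function(tr, times_fs) {
  idx <- findInterval(times_fs + 1e-9, tr$times_fs)
  idx[idx < 1L] <- 1L
  tr$active[pmin(idx, length(tr$active))]
}

#' Electronic-state populations over time
#'
#' P_k(t) is the fraction of trajectories whose active state is k at t.
#' Trajectories that terminated early either hold their last active
#' state (`early = "hold"`, default) or are dropped from the ensemble
#' (`early = "drop"`).
#'
#' @param trajectories a `trajectory_ensemble` or list of trajectories.
#' @param grid_fs time grid (fs); defaults to the frame times of the
#'   first trajectory.
#' @param confidence level for the binomial half-widths.
#' @param early early-termination handling: "hold" or "drop".
#' @return object of class `population_curve`: `times_fs`,
#'   `populations` (times x states), `ci_half_width`, `n_traj`.
#' @export
populations <- function(trajectories, grid_fs = NULL, confidence = 0.95,
                        early = c("hold", "drop")) {
  stop_if(length(trajectories) == 0, "no trajectories")
  early <- match.arg(early)
  if (early == "drop") {
    trajectories <- Filter(function(tr) tr$termination == "completed",
                           trajectories)
    stop_if(length(trajectories) == 0, "no completed trajectories")
  }
  grid_fs <- grid_fs %||% trajectories[[1]]$times_fs
  S <- ncol(trajectories[[1]]$energies)
  n <- length(trajectories)
  counts <- matrix(0L, length(grid_fs), S)
  for (tr in trajectories) {
    a <- active_at(tr, grid_fs)
    for (s in seq_len(S)) counts[, s] <- counts[, s] + (a == s)
  }
  p <- counts / n
  structure(list(times_fs = grid_fs, populations = p,
                 ci_half_width = binomial_ci(p, n, confidence),
                 n_traj = n, confidence = confidence,
                 state_names = paste0("S", seq_len(S) - 1L)),
            class = "population_curve")
}

#' @export
print.population_curve <- function(x, ...) {
  cat(sprintf("Population curve: %d states, %d grid points, %d trajectories\n",
              ncol(x$populations), length(x$times_fs), x$n_traj))
  nf <- length(x$times_fs)
  cat(sprintf("  final populations (t = %.1f fs): %s\n", x$times_fs[nf],
              paste(sprintf("%s=%.3f", x$state_names, x$populations[nf, ]),
                    collapse = " ")))
  invisible(x)
}

#' @export
plot.population_curve <- function(x, states = seq_len(ncol(x$populations)),
                                  ...) {
  graphics::matplot(x$times_fs, x$populations[, states, drop = FALSE],
                    type = "l", lty = 1, ylim = c(0, 1),
                    xlab = "time (fs)", ylab = "population", ...)
  for (j in seq_along(states)) {
    s <- states[j]
    graphics::polygon(c(x$times_fs, rev(x$times_fs)),
                      c(pmin(1, x$populations[, s] + x$ci_half_width[, s]),
                        rev(pmax(0, x$populations[, s] - x$ci_half_width[, s]))),
                      border = NA, col = grDevices::adjustcolor(j, alpha.f = 0.2))
  }
  graphics::legend("right", x$state_names[states], col = seq_along(states),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Bootstrap standard errors for populations (and derived scalars)
#'
#' Resamples trajectories with replacement (`round(fraction * n)` per
#' replicate) and returns the standard deviation over replicates of the
#' per-time populations; a caller-supplied reducer
#' `function(trajectories) -> numeric` can be bootstrapped the same way.
#'
#' @param trajectories trajectory list.
#' @param grid_fs time grid (fs).
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param fraction resample-size fraction in (0, 1\].
#' @param seed RNG seed.
#' @param reducer optional scalar/vector statistic to bootstrap instead
#'   of the population matrix.
#' @return for populations: times x states matrix of standard errors;
#'   for a reducer: vector of standard errors.
#' @export
bootstrap_populations <- function(trajectories, grid_fs = NULL, n_boot = 1000,
                                  fraction = 1, seed = 1, reducer = NULL) {
  stop_if(n_boot < 2, "need at least 2 bootstrap replicates")
  stop_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]")
  n <- length(trajectories)
  m <- max(1L, round(fraction * n))
  set.seed(seed)
  if (is.null(reducer)) {
    grid_fs <- grid_fs %||% trajectories[[1]]$times_fs
    S <- ncol(trajectories[[1]]$energies)
    ## precompute per-trajectory state indicators on the grid
    A <- vapply(trajectories, function(tr) active_at(tr, grid_fs),
                integer(length(grid_fs)))
    A <- matrix(A, length(grid_fs), n)
    acc <- array(0, c(length(grid_fs), S, 2))  # sum and sum of squares
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, m, replace = TRUE)
      Ab <- A[, idx, drop = FALSE]
      for (s in seq_len(S)) {
        ps <- rowMeans(Ab == s)
        acc[, s, 1] <- acc[, s, 1] + ps
        acc[, s, 2] <- acc[, s, 2] + ps^2
      }
    }
    mu <- acc[, , 1] / n_boot
    se <- sqrt(pmax(0, acc[, , 2] / n_boot - mu^2) * n_boot / (n_boot - 1))
    matrix(se, length(grid_fs), S)
  } else {
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, m, replace = TRUE)
      as.numeric(reducer(trajectories[idx]))
    }, numeric(length(reducer(trajectories))))
    if (is.null(dim(reps))) stats::sd(reps) else apply(reps, 1, stats::sd)
  }
}

#' Fit a (delayed) exponential rise to a population curve
#'
#' Plain form: P(t) = 1 - exp(-t / tau).  Delayed form:
#' P(t) = 1 - exp(-(t - t0) / tau) for t >= t0 and 0 before, with tau the
#' deactivation timescale and t0 the lag time.  Nonlinear least squares;
#' standard errors come from the fit covariance, or from a bootstrap
#' over trajectories when `boot_se` is supplied.
#'
#' @param curve a `population_curve` (or list with `times_fs` and a
#'   population vector in `populations`).
#' @param state state column to fit (1-based; ground state = 1).
#' @param form "delayed" or "plain".
#' @param boot_se optional externally computed standard errors
#'   (named tau/t0) that override the covariance-based ones.
#' @return object of class `decay_fit` with `tau`, `t0`, `tau_se`,
#'   `t0_se` (fs) and `model_form`.
#' @export
fit_decay <- function(curve, state = 1, form = c("delayed", "plain"),
                      boot_se = NULL) {
  form <- match.arg(form)
  t <- curve$times_fs
  p <- curve$populations[, state]
  if (max(p) < 0.5)
    warning("population rise covers less than half of the asymptote; fit may be ill-conditioned")
  ## initial guesses: tau from the time to reach 1 - 1/e of the final
  ## plateau; t0 from the first time P exceeds 0.02
  plateau <- max(p)
  t0_guess <- if (any(p > 0.02)) t[which(p > 0.02)[1]] else 0
  tau_level <- plateau * (1 - exp(-1))
  tau_guess <- max(t[which(p >= tau_level)[1]] - t0_guess, diff(range(t)) / 20,
                   na.rm = TRUE)
  df <- data.frame(t = t, p = p)
  fit <- tryCatch({
    if (form == "delayed") {
      minpack.lm::nlsLM(p ~ ifelse(t >= t0, 1 - exp(-(t - t0) / tau), 0),
                        data = df,
                        start = list(tau = tau_guess, t0 = max(t0_guess, 1e-3)),
                        lower = c(tau = 1e-8, t0 = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(p ~ 1 - exp(-t / tau), data = df,
                        start = list(tau = tau_guess), lower = c(tau = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) {
    stop(sprintf("decay fit did not converge (start: tau=%.3g, t0=%.3g): %s",
                 tau_guess, t0_guess, conditionMessage(e)), call. = FALSE)
  })
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  out <- list(tau = unname(cf["tau"]),
              t0 = if (form == "delayed") unname(cf["t0"]) else 0,
              tau_se = unname(boot_se["tau"] %||% se["tau"]),
              t0_se = if (form == "delayed") unname(boot_se["t0"] %||% se["t0"]) else 0,
              model_form = form, fit = fit)
  structure(out, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%s exponential fit: tau = %.2f +/- %.2f fs",
              x$model_form, x$tau, x$tau_se))
  if (x$model_form == "delayed")
    cat(sprintf(", t0 = %.2f +/- %.2f fs", x$t0, x$t0_se))
  cat("\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  if (object$model_form == "delayed") c(tau = object$tau, t0 = object$t0)
  else c(tau = object$tau)
}

#' @export
predict.decay_fit <- function(object, times_fs, ...) {
  if (object$model_form == "delayed") {
    ifelse(times_fs >= object$t0,
           1 - exp(-(times_fs - object$t0) / object$tau), 0)
  } else 1 - exp(-times_fs / object$tau)
}

## ---------------------------------------------------------------------------
## geometry measures and product classification

#' Distance, angle or dihedral from a geometry
#'
#' Distances in angstrom, angles and dihedrals in degrees; dihedrals are
#' signed in (-180, 180] and mirror-antisymmetric.
#'
#' @param geometry `n_atoms x 3` coordinate matrix.
#' @param kind "distance" (2 atoms), "angle" (3) or "dihedral" (4).
#' @param atoms atom indices (1-based).
#' @param unit unit of `geometry` coordinates ("bohr" or "angstrom").
#' @return scalar value.
#' @export
measure_geometry <- function(geometry, kind = c("distance", "angle", "dihedral"),
                             atoms, unit = c("bohr", "angstrom")) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  geometry <- matrix(geometry, ncol = 3)
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  stop_if(length(atoms) != need,
          sprintf("%s needs %d atom indices", kind, need))
  stop_if(any(atoms < 1 | atoms > nrow(geometry)), "atom index out of range")
  g <- geometry[atoms, , drop = FALSE]
  if (unit == "bohr") g <- g * ANG_PER_BOHR
  if (kind == "distance") {
    return(sqrt(sum((g[1, ] - g[2, ])^2)))
  }
  if (kind == "angle") {
    u <- g[1, ] - g[2, ]; w <- g[3, ] - g[2, ]
    cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
    return(acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
  }
  b1 <- g[2, ] - g[1, ]; b2 <- g[3, ] - g[2, ]; b3 <- g[4, ] - g[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  stop_if(sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20,
          "dihedral undefined: collinear atoms")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2); y <- sum(m1 * n2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Photoproduct classifier specification
#'
#' Threshold rules on a single geometric coordinate.  `kind = "distance"`
#' labels `label_above` when the distance strictly exceeds `threshold`
#' (ring-opening fingerprints such as a bond length above 1.8 angstrom);
#' `kind = "dihedral"` labels `label_below` when |dihedral| is strictly
#' below `threshold` (cis/trans switches such as a 60-degree rule);
#' `kind = "coordinate"` thresholds a raw coordinate entry (model
#' systems).  Ties go to the non-reactive class (strict inequalities).
#'
#' @param kind "distance", "dihedral" or "coordinate".
#' @param atoms atom indices (or coordinate index for "coordinate").
#' @param threshold threshold (angstrom, degrees, or bohr).
#' @param label_above,label_below class labels.
#' @param unit unit of trajectory coordinates ("bohr" default).
#' @return list of class `classifier_rule`.
#' @export
classifier_rule <- function(kind = c("distance", "dihedral", "coordinate"),
                            atoms, threshold,
                            label_above = "open", label_below = "closed",
                            unit = "bohr") {
  kind <- match.arg(kind)
  structure(list(kind = kind, atoms = atoms, threshold = threshold,
                 label_above = label_above, label_below = label_below,
                 unit = unit),
            class = "classifier_rule")
}

#' Classify a final geometry into a photoproduct label
#'
#' @param final_geometry coordinate matrix/vector (trajectory units).
#' @param rule a [classifier_rule()].
#' @return character label.
#' @export
classify_product <- function(final_geometry, rule) {
  stopifnot(inherits(rule, "classifier_rule"))
  val <- switch(rule$kind,
    distance = measure_geometry(final_geometry, "distance", rule$atoms,
                                unit = rule$unit),
    dihedral = abs(measure_geometry(final_geometry, "dihedral", rule$atoms,
                                    unit = rule$unit)),
    coordinate = {
      stop_if(rule$atoms > length(final_geometry), "atom index out of range")
      as.numeric(final_geometry)[rule$atoms]
    })
  if (rule$kind == "dihedral") {
    if (val < rule$threshold) rule$label_below else rule$label_above
  } else {
    if (val > rule$threshold) rule$label_above else rule$label_below
  }
}

#' Quantum yield of a photoproduct
#'
#' Phi = N_reactive / N_traj, the fraction of trajectories whose final
#' geometry classifies as the reactive label, with a binomial confidence
#' half-width.  Trajectories flagged distorted or uncertainty-terminated
#' are excluded from classification.
#'
#' @param trajectories trajectory list.
#' @param rule a [classifier_rule()].
#' @param reactive_label label counted as reactive (defaults to the
#'   rule's `label_above` for distance rules, `label_below` for dihedral
#'   rules).
#' @param confidence confidence level.
#' @return object of class `yield_result` (`phi`, `ci_half_width`,
#'   `n_reactive`, `n_traj`).
#' @export
quantum_yield <- function(trajectories, rule, reactive_label = NULL,
                          confidence = 0.95) {
  stop_if(length(trajectories) == 0, "no trajectories")
  reactive_label <- reactive_label %||%
    if (rule$kind == "dihedral") rule$label_below else rule$label_above
  keep <- Filter(function(tr)
    !tr$termination %in% c("distorted", "uncertainty_exceeded",
                           "numeric_failure"), trajectories)
  stop_if(length(keep) == 0, "all trajectories excluded by termination flags")
  labels <- vapply(keep, function(tr) {
    classify_product(tr$coords[nrow(tr$coords), ], rule)
  }, "")
  n <- length(keep)
  nr <- sum(labels == reactive_label)
  structure(list(phi = nr / n,
                 ci_half_width = binomial_ci(nr / n, n, confidence),
                 n_reactive = nr, n_traj = n,
                 reactive_label = reactive_label),
            class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("Quantum yield: Phi = %.3f +/- %.3f (%d reactive of %d)\n",
              x$phi, x$ci_half_width, x$n_reactive, x$n_traj))
  invisible(x)
}

#' Hop-geometry statistics table
#'
#' One row per accepted hop of the requested state pair, with the hop
#' time, the requested geometric measures at the hop geometry, and the
#' trajectory's final product label; per-product mean hop times are
#' attached as an attribute.
#'
#' @param trajectories trajectory list.
#' @param pair integer pair (j, k) of states; hops j->k and k->j both
#'   count.
#' @param measures named list; each element is either a list
#'   `(kind, atoms)` for [measure_geometry()] or a
#'   `function(geometry) -> value`.
#' @param rule optional [classifier_rule()] for the product label.
#' @return data frame (class `hop_table`) with attribute
#'   `product_means` (mean hop time per product).
#' @export
hop_statistics <- function(trajectories, pair, measures = list(),
                           rule = NULL) {
  rows <- list()
  for (ti in seq_along(trajectories)) {
    tr <- trajectories[[ti]]
    h <- tr$hops
    h <- h[h$accepted &
           ((h$from_state == pair[1] & h$to_state == pair[2]) |
            (h$from_state == pair[2] & h$to_state == pair[1])), , drop = FALSE]
    if (nrow(h) == 0) next
    label <- if (!is.null(rule))
      classify_product(tr$coords[nrow(tr$coords), ], rule) else NA_character_
    for (j in seq_len(nrow(h))) {
      geom <- tr$coords[h$frame[j], ]
      vals <- lapply(measures, function(m) {
        if (is.function(m)) m(geom)
        else measure_geometry(geom, m$kind, m$atoms, unit = m$unit %||% "bohr")
      })
      rows[[length(rows) + 1L]] <- data.frame(
        trajectory = ti, time_fs = h$time_fs[j],
        from_state = h$from_state[j], to_state = h$to_state[j],
        as.list(setNames(vals, names(measures))), product = label,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trajectory = integer(0), time_fs = numeric(0),
               from_state = integer(0), to_state = integer(0),
               product = character(0))
  means <- if (nrow(tab) > 0 && !all(is.na(tab$product)))
    tapply(tab$time_fs, tab$product, mean) else NULL
  structure(tab, product_means = means, class = c("hop_table", "data.frame"))
}

#' Branching ratio near the conical intersection
#'
#' Among accepted hops whose dihedral lies within `window_halfwidth` of
#' the CI dihedral, counts the two product labels and reports their
#' ratio Gamma = 1 : (n_other / n_first); the fraction of hops outside
#' the window is reported separately.
#'
#' @param hop_table a [hop_statistics()] table containing the dihedral
#'   measure and product labels.
#' @param ci_dihedral CI dihedral angle (degrees).
#' @param window_halfwidth window half-width (degrees, default 20).
#' @param dihedral_col column name holding the dihedral.
#' @param first_label product label reported first in the ratio.
#' @return object of class `branching_result` (`gamma`, `n_inside`,
#'   `n_outside`, `fraction_outside`, per-label counts).
#' @export
branching_ratio <- function(hop_table, ci_dihedral, window_halfwidth = 20,
                            dihedral_col = "dihedral", first_label = NULL) {
  stop_if(!dihedral_col %in% names(hop_table),
          sprintf("hop table has no '%s' column", dihedral_col))
  d <- hop_table[[dihedral_col]]
  inside <- abs(d - ci_dihedral) <= window_halfwidth
  labs <- hop_table$product
  tab_in <- table(labs[inside])
  first_label <- first_label %||% names(tab_in)[1]
  n_first <- sum(labs[inside] == first_label)
  n_other <- sum(inside) - n_first
  gamma <- if (n_first > 0) n_other / n_first else NA_real_
  if (is.na(gamma) && sum(inside) == 0)
    warning("no hops inside the CI window: branching ratio undefined")
  structure(list(gamma = gamma, first_label = first_label,
                 n_inside = sum(inside), n_outside = sum(!inside),
                 fraction_outside = mean(!inside),
                 counts_inside = tab_in,
                 window_halfwidth = window_halfwidth),
            class = "branching_result")
}

#' @export
print.branching_result <- function(x, ...) {
  if (is.na(x$gamma)) {
    cat("Branching ratio undefined (no hops inside the CI window)\n")
  } else {
    cat(sprintf("Branching ratio near CI: %s : other = 1 : %.2f (%d hops inside, %.1f%% outside)\n",
                x$first_label, x$gamma, x$n_inside,
                100 * x$fraction_outside))
  }
  invisible(x)
}

#' Linearly interpolated path between two geometries
#'
#' @param geometry_a,geometry_b coordinate vectors of equal length.
#' @param n_points number of path points (>= 2), endpoints included.
#' @return list of coordinate vectors, evenly spaced in Cartesian space.
#' @export
liic_path <- function(geometry_a, geometry_b, n_points) {
  a <- as.numeric(geometry_a); b <- as.numeric(geometry_b)
  stop_if(length(a) != length(b), "geometry dimension mismatch")
  stop_if(n_points < 2, "need at least the two endpoints")
  lapply(seq(0, 1, length.out = n_points), function(s) (1 - s) * a + s * b)
}
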