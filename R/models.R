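#' Analytic diabatic model potentials
#'
#' A `diabatic_model` packages a real symmetric diabatic potential matrix
#' V(x) with its analytic coordinate derivatives.  Diagonalizing V(x)
#' yields the adiabatic surfaces on which trajectories are propagated;
#' Hellmann-Feynman contraction of dV/dx with the eigenvectors yields the
#' adiabatic gradients.  These models play the role of the reference
#' electronic-structure method: they label training data for surrogates
#' and serve as ground truth in every test.
#'
#' @param name identifier string.
#' @param n_coords number of nuclear coordinates.
#' @param n_states number of electronic states (>= 2).
#' @param masses per-coordinate masses, atomic units (electron masses).
#' @param params named list of real parameters.
#' @param vfun function(x, params) returning the n_states x n_states
#'   symmetric diabatic matrix (hartree).
#' @param dvfun function(x, params) returning an array
#'   `n_states x n_states x n_coords` of dV/dx (hartree/bohr).
#' @return object of class `diabatic_model`.
#' @export
diabatic_model <- function(name, n_coords, n_states, masses, params, vfun, dvfun) {
  stop_if(n_states < 2, "a diabatic model needs at least 2 electronic states")
  stop_if(length(masses) != n_coords, "need one mass per coordinate")
  stop_if(any(!is.finite(masses)) || any(masses <= 0), "all masses must be positive")
  ## symmetry is part of the contract; spot-check at a generic point
  x0 <- rep(0.1234, n_coords)
  v0 <- vfun(x0, params)
  stop_if(!isTRUE(all.equal(v0, t(v0), tolerance = 1e-12)),
          "diabatic matrix V(x) must be symmetric")
  structure(list(name = name, n_coords = n_coords, n_states = n_states,
                 masses = as.numeric(masses), params = params,
                 vfun = vfun, dvfun = dvfun),
            class = "diabatic_model")
}

#' @export
print.diabatic_model <- function(x, ...) {
  cat(sprintf("Diabatic model '%s': %d state(s), %d coordinate(s)\n",
              x$name, x$n_states, x$n_coords))
  cat("  masses (a.u.):", paste(signif(x$masses, 6), collapse = ", "), "\n")
  cat("  parameters:", paste(names(x$params), unlist(lapply(x$params, function(p)
    paste(signif(p, 6), collapse = ","))), sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Diabatic matrix of a model at a geometry
#' @param model a `diabatic_model`.
#' @param x coordinate vector (bohr).
#' @return symmetric matrix (hartree).
#' @export
diabatic_matrix <- function(model, x) {
  stop_if(length(x) != model$n_coords, "x has wrong length")
  model$vfun(as.numeric(x), model$params)
}

#' Adiabatic energies, gradients and gaps at a geometry
#'
#' Diagonalizes the diabatic matrix; energies are returned ascending.
#' Gradients are the Hellmann-Feynman derivatives u_k' dV/dx u_k of the
#' adiabatic states.  At an exact degeneracy the eigenvectors are not
#' unique; the one-sided gradients of the returned eigenbasis are kept
#' and `degenerate` is set instead of raising an error, so that seam
#' optimizers can still evaluate there.
#'
#' @param model a `diabatic_model`.
#' @param x coordinate vector (bohr).
#' @param with_gradients compute per-state gradients?
#' @param degeneracy_tol adjacent-gap threshold (hartree) below which the
#'   point is flagged degenerate.
#' @return an `adiabatic_point`: list with `energies` (ascending, hartree),
#'   `gradients` (n_states x n_coords, hartree/bohr, or NULL), `gaps`
#'   (matrix with Z\[j,k\] = E_k - E_j), `uncertainty` (zeros: analytic
#'   reference), `degenerate` flag.
#' @export
evaluate_adiabatic <- function(model, x, with_gradients = TRUE,
                               degeneracy_tol = 1e-10) {
  x <- as.numeric(x)
  stop_if(length(x) != model$n_coords, "x has wrong length for this model")
  stop_if(any(!is.finite(x)), "non-finite coordinates")
  v <- model$vfun(x, model$params)
  eg <- eigen(v, symmetric = TRUE)
  ord <- order(eg$values)            # eigen() returns decreasing; sort ascending
  e <- eg$values[ord]
  u <- eg$vectors[, ord, drop = FALSE]
  degenerate <- any(diff(e) < degeneracy_tol)
  grads <- NULL
  if (with_gradients) {
    dv <- model$dvfun(x, model$params)
    grads <- matrix(0, model$n_states, model$n_coords)
    for (d in seq_len(model$n_coords)) {
      grads[, d] <- colSums(u * (dv[, , d] %*% u))
    }
  }
  adiabatic_point(e, grads, uncertainty = rep(0, model$n_states),
                  degenerate = degenerate)
}

#' Construct an adiabatic point
#'
#' @param energies per-state energies (hartree); re-sorted ascending with
#'   `reordered = TRUE` if the input order was violated.
#' @param gradients optional n_states x n_coords matrix (hartree/bohr).
#' @param uncertainty optional per-state 1-sigma energy uncertainty.
#' @param degenerate flag: adjacent states (near-)degenerate here.
#' @return list of class `adiabatic_point` with a `gaps` matrix
#'   Z\[j,k\] = E_k - E_j.
#' @export
adiabatic_point <- function(energies, gradients = NULL, uncertainty = NULL,
                            degenerate = FALSE) {
  energies <- as.numeric(energies)
  reordered <- is.unsorted(energies)
  if (reordered) {
    ord <- order(energies)
    energies <- energies[ord]
    if (!is.null(gradients)) gradients <- gradients[ord, , drop = FALSE]
    if (!is.null(uncertainty)) uncertainty <- uncertainty[ord]
  }
  gaps <- outer(energies, energies, function(a, b) b - a)
  structure(list(energies = energies, gradients = gradients, gaps = gaps,
                 uncertainty = uncertainty %||% rep(0, length(energies)),
                 degenerate = degenerate, reordered = reordered),
            class = "adiabatic_point")
}

#' @export
print.adiabatic_point <- function(x, ...) {
  cat("Adiabatic point:", length(x$energies), "state(s)\n")
  cat("  E (hartree):", paste(sprintf("%.8f", x$energies), collapse = " "), "\n")
  if (!is.null(x$gradients)) cat("  gradients available\n")
  if (x$degenerate) cat("  (degenerate)\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Shipped models

#' One-dimensional linear crossing model
#'
#' Two diabats with slopes +/- `slope` crossing at x = 0, coupled by a
#' constant `coupling`.  Its single-passage dynamics admit the exact
#' Landau-Zener transition probability, making it the analytic oracle for
#' the hopping algorithm.  The adiabatic gap along a constant-velocity
#' path is Z(t) = sqrt((2*slope*v*t)^2 + 4*coupling^2).
#'
#' @param slope F in V11 = F x, V22 = -F x (hartree/bohr).
#' @param coupling constant off-diagonal H12 (hartree).
#' @param mass particle mass (a.u.).
#' @return a `diabatic_model`.
#' @export
model_linear_crossing <- function(slope = 0.01, coupling = 0.005, mass = 2000) {
  p <- list(slope = slope, coupling = coupling)
  diabatic_model(
    "linear_crossing", 1L, 2L, mass, p,
    vfun = function(x, p) matrix(c(p$slope * x, p$coupling,
                                   p$coupling, -p$slope * x), 2, 2),
    dvfun = function(x, p) array(c(p$slope, 0, 0, -p$slope), c(2, 2, 1)))
}

#' Single avoided crossing model (Tully-style)
#'
#' @param a,b,c,d shape parameters (a.u.): V11 = a(1-exp(-b x)) for x>=0,
#'   -a(1-exp(b x)) for x<0; V22 = -V11; V12 = c exp(-d x^2).
#' @param mass particle mass (a.u.).
#' @return a `diabatic_model`.
#' @export
model_avoided_crossing <- function(a = 0.01, b = 1.6, c = 0.005, d = 1.0,
                                   mass = 2000) {
  p <- list(a = a, b = b, c = c, d = d)
  v11 <- function(x, p) ifelse(x >= 0, p$a * (1 - exp(-p$b * x)),
                               -p$a * (1 - exp(p$b * x)))
  dv11 <- function(x, p) p$a * p$b * exp(-p$b * abs(x))
  diabatic_model(
    "avoided_crossing", 1L, 2L, mass, p,
    vfun = function(x, p) {
      v1 <- v11(x, p); v12 <- p$c * exp(-p$d * x^2)
      matrix(c(v1, v12, v12, -v1), 2, 2)
    },
    dvfun = function(x, p) {
      g1 <- dv11(x, p); g12 <- -2 * p$d * x * p$c * exp(-p$d * x^2)
      array(c(g1, g12, g12, -g1), c(2, 2, 1))
    })
}

#' Three-state, two-coordinate vibronic coupling model
#'
#' Diabats along a tuning coordinate x1 and a coupling coordinate x2:
#'   V_kk = k/2 (x1^2 + x2^2) + q/4 (x1^4 + x2^4) + kappa_k x1 + eps_k,
#' with linear couplings lambda x2 between every state pair.  The default
#' parameters place the S2/S1 diabatic crossing at x1 = 2/3 bohr and the
#' S1/S0 crossing at x1 = 4/3 bohr, both reachable downhill from the
#' Franck-Condon point, so a wavepacket launched on S2 cascades
#' S2 -> S1 -> S0 as in a pericyclic photoreaction.  True conical
#' intersections (gap -> 0) occur on the x2 = 0 line.  The small
#' state-independent quartic term `q` leaves every crossing in place but
#' makes the vibrational period amplitude-dependent, giving the ensemble
#' the vibrational dephasing that a multidimensional molecule has (a
#' strictly harmonic model is isochronous and shows unphysically
#' persistent coherent recurrences).
#'
#' @param k harmonic force constant (hartree/bohr^2), same for all modes.
#' @param q quartic anharmonicity (hartree/bohr^4), same for all states.
#' @param eps per-state vertical offsets (hartree).
#' @param kappa per-state linear tuning slopes (hartree/bohr).
#' @param lambda linear diabatic coupling constant (hartree/bohr).
#' @param mass per-coordinate mass (a.u.).
#' @return a `diabatic_model`.
#' @export
model_lvc3 <- function(k = 0.05, q = 0.008, eps = c(0, 0.08, 0.12),
                       kappa = c(0, -0.06, -0.12), lambda = 0.03,
                       mass = 2000) {
  stop_if(length(eps) != 3 || length(kappa) != 3, "eps and kappa need 3 entries")
  p <- list(k = k, q = q, eps = eps, kappa = kappa, lambda = lambda)
  diabatic_model(
    "lvc3", 2L, 3L, rep(mass, 2), p,
    vfun = function(x, p) {
      h <- 0.5 * p$k * sum(x^2) + 0.25 * p$q * sum(x^4)
      v <- diag(h + p$kappa * x[1] + p$eps)
      cpl <- p$lambda * x[2]
      v[1, 2] <- v[2, 1] <- cpl
      v[2, 3] <- v[3, 2] <- cpl
      v[1, 3] <- v[3, 1] <- cpl
      v
    },
    dvfun = function(x, p) {
      dv <- array(0, c(3, 3, 2))
      diag(dv[, , 1]) <- p$k * x[1] + p$q * x[1]^3 + p$kappa
      diag(dv[, , 2]) <- p$k * x[2] + p$q * x[2]^3
      dv[1, 2, 2] <- dv[2, 1, 2] <- p$lambda
      dv[2, 3, 2] <- dv[3, 2, 2] <- p$lambda
      dv[1, 3, 2] <- dv[3, 1, 2] <- p$lambda
      dv
    })
}

#' Normal-mode specification of the lvc3 model ground-state well
#'
#' Harmonic frequencies omega = sqrt(k/m) for both modes about the S0
#' diabatic minimum at the origin, for use with [wigner_sample()].
#'
#' @param model a model built by [model_lvc3()].
#' @return a `normal_mode_spec`.
#' @export
lvc3_normal_modes <- function(model) {
  w <- sqrt(model$params$k / model$masses)
  normal_mode_spec(equilibrium_coords = c(0, 0), frequencies = w,
                   mode_vectors = diag(2), masses = model$masses)
}

#' Analytic Landau-Zener single-passage probability
#'
#' Closed form P = exp(-2 pi H12^2 / (hbar v |dF|)) for a constant-velocity
#' passage through a linear crossing; the independent oracle against which
#' the gap-based hopping probability is validated.
#'
#' @param h12 diabatic coupling (hartree), > 0.
#' @param slope_diff difference of diabatic slopes |dF| (hartree/bohr), > 0.
#' @param speed nuclear speed at the crossing (bohr / atomic time), > 0.
#' @return probability in (0, 1).
#' @export
landau_zener_reference <- function(h12, slope_diff, speed) {
  stop_if(!is.finite(h12) || h12 <= 0, "h12 must be > 0")
  stop_if(!is.finite(slope_diff) || slope_diff <= 0, "slope_diff must be > 0")
  stop_if(!is.finite(speed) || speed <= 0,
          "speed must be > 0 (the zero-speed limit is not defined here)")
  exp(-2 * pi * h12^2 / (speed * slope_diff))
}

## ---------------------------------------------------------------------------
## Fixture data sets

#' Generate a labeled training set from a model potential
#'
#' Draws geometries uniformly from a box and labels them with the model's
#' adiabatic energies (and gradients, unless `include_gradients = FALSE`
#' -- the energy-only condition).  Stands in for re-labeling molecular
#' conformations at a given level of theory.
#'
#' @param model a `diabatic_model` (or anything accepted by
#'   [eval_potential()]).
#' @param n number of configurations.
#' @param lower,upper per-coordinate bounds of the sampling box (bohr).
#' @param seed RNG seed.
#' @param fidelity fidelity tag attached to every record.
#' @param include_gradients store per-state gradients?
#' @return list of class `labeled_dataset`; each record has `coords`,
#'   `fidelity`, `energies`, `gradients` (or NULL), `weight`.
#' @export
make_fixture_dataset <- function(model, n, lower, upper, seed,
                                 fidelity = "reference",
                                 include_gradients = TRUE) {
  stop_if(n <= 0, "need a positive number of configurations")
  nc <- model$n_coords
  lower <- rep_len(as.numeric(lower), nc)
  upper <- rep_len(as.numeric(upper), nc)
  stop_if(any(upper <= lower), "empty sampling range")
  set.seed(seed)
  xs <- matrix(stats::runif(n * nc, rep(lower, each = n), rep(upper, each = n)),
               n, nc)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    ap <- eval_potential(model, xs[i, ], gradients = include_gradients)
    records[[i]] <- list(coords = xs[i, ], fidelity = fidelity,
                         energies = ap$energies,
                         gradients = if (include_gradients) ap$gradients else NULL,
                         weight = 1)
  }
  labeled_dataset(records)
}

#' Bundle labeled records into a dataset
#' @param records list of records (coords, fidelity, energies,
#'   gradients or NULL, weight).
#' @return the list with class `labeled_dataset`.
#' @export
labeled_dataset <- function(records) {
  stop_if(length(records) == 0, "empty dataset")
  for (r in records) {
    stop_if(is.null(r$coords) || is.null(r$energies) || is.null(r$fidelity),
            "each record needs coords, energies and a fidelity tag")
    if (!is.null(r$gradients)) {
      stop_if(!all(dim(r$gradients) == c(length(r$energies), length(r$coords))),
              "gradient block must be n_states x n_coords")
    }
  }
  structure(records, class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  fids <- vapply(x, function(r) r$fidelity, "")
  has_g <- vapply(x, function(r) !is.null(r$gradients), TRUE)
  cat(sprintf("Labeled dataset: %d records, %d state(s), %d coordinate(s)\n",
              length(x), length(x[[1]]$energies), length(x[[1]]$coords)))
  for (f in unique(fids)) {
    cat(sprintf("  fidelity '%s': %d records (%s gradients)\n", f,
                sum(fids == f),
                if (all(has_g[fids == f])) "with" else "without"))
  }
  invisible(x)
}

#' Merge labeled datasets (e.g. several fidelities)
#' @param ... `labeled_dataset` objects.
#' @return a combined `labeled_dataset`.
#' @export
merge_datasets <- function(...) {
  labeled_dataset(do.call(c, lapply(list(...), unclass)))
}
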