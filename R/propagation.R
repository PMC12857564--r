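#' Surface-hopping trajectory propagation
#'
#' Velocity-Verlet integration on the active adiabatic surface,
#' interleaved with coupling-free Landau-Zener-Belyaev-Lebedev (LZBL)
#' hopping: the adiabatic gap Z between the active state and each
#' adjacent state is monitored along the trajectory, and a hop is
#' attempted only at strict local minima of Z, with probability
#' P = exp(-(pi/2) * sqrt(Z^3 / Zdd)) (atomic units, hbar = 1), where
#' Zdd is the second time derivative of the gap estimated by a
#' three-point central difference.  Upward hops are vetoed when the
#' available kinetic energy cannot pay the gap (frustrated hops);
#' accepted hops rescale all velocities uniformly so total energy is
#' conserved exactly.
#'
#' @name propagation
NULL

#' Propagation settings
#'
#' @param dt_fs time step (fs).
#' @param t_max_fs total propagation time (fs).
#' @param reservoir_reduced if TRUE, the kinetic energy deemed available
#'   for upward hops is the total kinetic energy divided by the number of
#'   internal degrees of freedom; if FALSE, the total kinetic energy.
#' @param uncertainty_threshold per-state ensemble-uncertainty threshold
#'   (hartree) beyond which a trajectory is terminated (default 0.03).
#' @param distortion_check optional predicate `function(coords, coords0)`
#'   returning TRUE when the geometry is unphysically distorted.
#' @param n_dof number of internal degrees of freedom for the reduced
#'   reservoir (defaults to the number of coordinates).
#' @param seed RNG seed for the hopping stream.
#' @return list of class `propagation_settings`.
#' @export
propagation_settings <- function(dt_fs = 0.1, t_max_fs = 60,
                                 reservoir_reduced = FALSE,
                                 uncertainty_threshold = 0.03,
                                 distortion_check = NULL, n_dof = NULL,
                                 seed = 1) {
  stop_if(dt_fs <= 0, "dt must be positive")
  stop_if(t_max_fs < dt_fs, "t_max must be at least one step")
  structure(list(dt_fs = dt_fs, t_max_fs = t_max_fs,
                 reservoir_reduced = reservoir_reduced,
                 uncertainty_threshold = uncertainty_threshold,
                 distortion_check = distortion_check, n_dof = n_dof,
                 seed = seed),
            class = "propagation_settings")
}

#' Geometry-distortion predicate for pairwise distances
#'
#' Returns a predicate flagging geometries in which any pairwise
#' distance leaves `[lo, hi]` times its initial value.  Intended for
#' molecular coordinates laid out as an `n_atoms x 3` matrix.
#'
#' @param lo,hi allowed range as multiples of the initial distances.
#' @return function(coords, coords0) -> logical.
#' @export
distortion_distance_check <- function(lo = 0.5, hi = 5) {
  function(coords, coords0) {
    d0 <- stats::dist(matrix(coords0, ncol = 3))
    d1 <- stats::dist(matrix(coords, ncol = 3))
    any(d1 < lo * d0 | d1 > hi * d0)
  }
}

#' One velocity-Verlet step on the active surface
#'
#' @param state list with `coords`, `velocities`, `active_state`, and
#'   optionally `t` (atomic units).
#' @param potential any multi-state potential.
#' @param dt time step (atomic units).
#' @param masses per-coordinate masses (a.u.).
#' @param fidelity fidelity tag for surrogate potentials.
#' @return updated state with re-evaluated `energies` and `point`
#'   (the [adiabatic_point()] at the new geometry).
#' @export
velocity_verlet_step <- function(state, potential, dt, masses,
                                 fidelity = NULL) {
  k <- state$active_state
  ap0 <- state$point %||% eval_potential(potential, state$coords,
                                         fidelity = fidelity, gradients = TRUE)
  f0 <- -ap0$gradients[k, ]
  stop_if(any(!is.finite(f0)), "non-finite force")
  v_half <- state$velocities + 0.5 * dt * f0 / masses
  x_new <- state$coords + dt * v_half
  ap1 <- eval_potential(potential, x_new, fidelity = fidelity, gradients = TRUE)
  f1 <- -ap1$gradients[k, ]
  v_new <- v_half + 0.5 * dt * f1 / masses
  list(t = (state$t %||% 0) + dt, coords = x_new, velocities = v_new,
       active_state = k, energies = ap1$energies, point = ap1)
}

#' Gap window over three consecutive steps
#'
#' @param z numeric length-3 gap values Z(t_(i-1)), Z(t_i), Z(t_(i+1))
#'   (hartree).
#' @param times their times (atomic units), strictly increasing and
#'   equally spaced.
#' @return list of class `gap_window`.
#' @export
gap_window <- function(z, times) {
  stop_if(length(z) != 3 || length(times) != 3, "need exactly three points")
  dt <- diff(times)
  stop_if(any(dt <= 0) || abs(dt[1] - dt[2]) > 1e-9 * dt[1],
          "times must be strictly increasing and equally spaced")
  structure(list(z = as.numeric(z), times = as.numeric(times),
                 dt = dt[1]), class = "gap_window")
}

#' Is the middle point a strict local gap minimum?
#'
#' Strict inequalities on both sides; plateaus never trigger.
#'
#' @param window a [gap_window()].
#' @return logical flag.
#' @export
detect_gap_minimum <- function(window) {
  z <- window$z
  z[1] > z[2] && z[2] < z[3]
}

#' LZBL hopping probability at a gap minimum
#'
#' P = exp(-(pi/2) * sqrt(Z^3 / Zdd)) with the second time derivative of
#' the gap estimated by the three-point central difference
#' (Z_(i-1) - 2 Z_i + Z_(i+1)) / dt^2.  An exact degeneracy (Z = 0)
#' gives P = 1.  Must only be called at a detected gap minimum.
#'
#' @param window a [gap_window()] for which [detect_gap_minimum()] holds.
#' @param dt time step (atomic units); defaults to the window spacing.
#' @return probability in \[0, 1\].
#' @export
lzbl_probability <- function(window, dt = window$dt) {
  stop_if(!detect_gap_minimum(window),
          "lzbl_probability called off a gap minimum (contract violation)")
  z <- window$z[2]
  if (z <= 0) return(1)
  zdd <- (window$z[1] - 2 * window$z[2] + window$z[3]) / dt^2
  stop_if(zdd <= 0, "non-positive gap curvature at a detected minimum")
  min(1, max(0, exp(-(pi / 2) * sqrt(z^3 / zdd))))
}

#' Uniform velocity rescaling across a hop
#'
#' Scales all velocities by sqrt(1 + delta_e / KE) so the kinetic energy
#' changes by exactly `delta_e` and total energy is conserved across the
#' hop.
#'
#' @param velocities velocity vector (bohr / atomic time).
#' @param masses per-coordinate masses (a.u.).
#' @param delta_e potential-energy release E_old - E_new (hartree);
#'   negative for upward hops, which must have been vetoed upstream if
#'   KE + delta_e < 0.
#' @return rescaled velocity vector.
#' @export
rescale_velocities <- function(velocities, masses, delta_e) {
  ke <- 0.5 * sum(masses * velocities^2)
  if (delta_e == 0) return(velocities)
  stop_if(ke + delta_e < 0,
          "kinetic energy cannot absorb delta_e (should have been vetoed as frustrated)")
  velocities * sqrt(1 + delta_e / ke)
}

#' Attempt a stochastic hop
#'
#' Draws one uniform variate from the current RNG stream; the hop is
#' accepted iff the draw falls below `p` and (for upward hops) the
#' available kinetic energy covers the gap.  Energetically vetoed
#' attempts are recorded as frustrated.
#'
#' @param state list with `coords`, `velocities`, `active_state`,
#'   `energies`, and optionally `t`.
#' @param target target state index.
#' @param p hop probability in \[0, 1\].
#' @param masses per-coordinate masses.
#' @param reservoir_reduced use the reduced kinetic-energy reservoir?
#' @param n_dof internal degrees of freedom for the reduced reservoir.
#' @param u uniform variate deciding the hop (defaults to a fresh draw;
#'   [propagate()] supplies one pregenerated variate per time step so
#'   that paired runs on nearby potentials stay synchronized).
#' @return list with the (possibly updated) `state` and an `event` list
#'   (`time`, `from_state`, `to_state`, `probability`, `accepted`,
#'   `frustrated`).
#' @export
attempt_hop <- function(state, target, p, masses, reservoir_reduced = FALSE,
                        n_dof = length(state$coords), u = stats::runif(1)) {
  stop_if(p < 0 || p > 1, "probability outside [0, 1]")
  k <- state$active_state
  stop_if(target == k, "target equals active state")
  ev <- list(time = state$t %||% 0, from_state = k, to_state = target,
             probability = p, accepted = FALSE, frustrated = FALSE)
  if (u < p) {
    delta_e <- state$energies[k] - state$energies[target]
    ke <- 0.5 * sum(masses * state$velocities^2)
    avail <- if (reservoir_reduced) ke / max(1L, n_dof) else ke
    if (delta_e < 0 && avail < -delta_e) {
      ev$frustrated <- TRUE
    } else {
      state$velocities <- rescale_velocities(state$velocities, masses, delta_e)
      state$active_state <- target
      ev$accepted <- TRUE
    }
  }
  list(state = state, event = ev)
}

#' Propagate one surface-hopping trajectory
#'
#' Alternates velocity-Verlet steps with gap-minimum monitoring for all
#' state pairs adjacent to the active state.  When two pairs minimize
#' simultaneously, the smaller gap is attempted first and only one
#' attempt is made per step.  The trajectory terminates at `t_max`, when
#' the potential's per-state uncertainty exceeds the threshold, when the
#' distortion predicate fires, or on numeric failure (returned as a
#' termination reason, never an exception).
#'
#' @param potential any multi-state potential.
#' @param initial list with `coords` (bohr), `velocities`
#'   (bohr/atomic time) and `state` (1-based; ground state = 1).
#' @param settings a [propagation_settings()].
#' @param masses per-coordinate masses; defaults to the potential's
#'   masses for analytic models.
#' @param fidelity fidelity tag for surrogate potentials.
#' @return object of class `trajectory`: `times_fs`, `coords`,
#'   `velocities`, `energies` (frames x states), `active` (per-frame
#'   active state), `uncertainty` (per-frame max), `hops` (data frame),
#'   `termination`, `masses`.
#' @export
propagate <- function(potential, initial, settings = propagation_settings(),
                      masses = NULL, fidelity = NULL) {
  if (is.null(masses)) {
    stop_if(!inherits(potential, "diabatic_model"),
            "masses must be given for surrogate potentials")
    masses <- potential$masses
  }
  x <- as.numeric(initial$coords)
  v <- as.numeric(initial$velocities)
  k <- as.integer(initial$state)
  S <- n_states(potential)
  nc <- length(x)
  stop_if(length(v) != nc || length(masses) != nc, "dimension mismatch")
  stop_if(k < 1 || k > S, "initial state out of range")
  dt <- fs_to_au(settings$dt_fs)
  n_steps <- as.integer(round(settings$t_max_fs / settings$dt_fs))
  n_dof <- settings$n_dof %||% nc
  evalf <- make_evaluator(potential, fidelity)
  ## one uniform per step, drawn up front: the variate consumed by a hop
  ## attempt at step i is fixed by (seed, i) alone, so paired runs on
  ## nearby potentials keep using common random numbers even when the
  ## detected gap minima differ slightly
  set.seed(settings$seed)
  hop_u <- stats::runif(n_steps)

  coords <- matrix(NA_real_, n_steps + 1L, nc)
  vels <- matrix(NA_real_, n_steps + 1L, nc)
  energies <- matrix(NA_real_, n_steps + 1L, S)
  active <- integer(n_steps + 1L)
  unc <- numeric(n_steps + 1L)
  hops <- list()
  termination <- "completed"

  ap <- evalf(x)
  coords[1L, ] <- x; vels[1L, ] <- v
  energies[1L, ] <- ap$energies; active[1L] <- k
  unc[1L] <- max(ap$uncertainty)
  x0 <- x
  f <- -ap$gradients[k, ]
  gaps_prev2 <- rep(NA_real_, S - 1L)
  gaps_prev1 <- rep(NA_real_, S - 1L)
  last_frame <- 1L

  for (i in seq_len(n_steps)) {
    if (any(!is.finite(f))) { termination <- "numeric_failure"; break }
    v_half <- v + 0.5 * dt * f / masses
    x <- x + dt * v_half
    ap <- evalf(x)
    if (any(!is.finite(ap$energies))) { termination <- "numeric_failure"; break }
    f <- -ap$gradients[k, ]
    v <- v_half + 0.5 * dt * f / masses
    gaps_cur <- diff(ap$energies)

    ## LZBL hop logic at strict gap minima of pairs adjacent to the active state
    cand <- integer(0)
    for (pr in c(k - 1L, k)) {
      if (pr >= 1L && pr <= S - 1L && !is.na(gaps_prev2[pr]) &&
          gaps_prev2[pr] > gaps_prev1[pr] && gaps_prev1[pr] < gaps_cur[pr]) {
        cand <- c(cand, pr)
      }
    }
    if (length(cand) > 0) {
      pr <- cand[which.min(gaps_prev1[cand])]
      w <- gap_window(c(gaps_prev2[pr], gaps_prev1[pr], gaps_cur[pr]),
                      c(-dt, 0, dt) + i * dt)
      p <- lzbl_probability(w, dt)
      target <- if (k == pr) pr + 1L else pr
      st <- list(t = i * dt, coords = x, velocities = v, active_state = k,
                 energies = ap$energies)
      res <- attempt_hop(st, target, p, masses,
                         reservoir_reduced = settings$reservoir_reduced,
                         n_dof = n_dof, u = hop_u[i])
      ev <- res$event
      hops[[length(hops) + 1L]] <- data.frame(
        time_fs = i * settings$dt_fs, from_state = ev$from_state,
        to_state = ev$to_state, probability = ev$probability,
        accepted = ev$accepted, frustrated = ev$frustrated,
        frame = i + 1L)
      if (ev$accepted) {
        k <- res$state$active_state
        v <- res$state$velocities
        f <- -ap$gradients[k, ]
        gaps_prev2[] <- NA_real_; gaps_prev1[] <- NA_real_
        gaps_cur <- diff(ap$energies)
      }
    }
    gaps_prev2 <- gaps_prev1
    gaps_prev1 <- gaps_cur

    coords[i + 1L, ] <- x; vels[i + 1L, ] <- v
    energies[i + 1L, ] <- ap$energies; active[i + 1L] <- k
    unc[i + 1L] <- max(ap$uncertainty)
    last_frame <- i + 1L

    if (unc[i + 1L] > settings$uncertainty_threshold) {
      termination <- "uncertainty_exceeded"; break
    }
    if (!is.null(settings$distortion_check) &&
        isTRUE(settings$distortion_check(x, x0))) {
      termination <- "distorted"; break
    }
  }

  keep <- seq_len(last_frame)
  hops_df <- if (length(hops)) do.call(rbind, hops) else
    data.frame(time_fs = numeric(0), from_state = integer(0),
               to_state = integer(0), probability = numeric(0),
               accepted = logical(0), frustrated = logical(0),
               frame = integer(0))
  structure(list(times_fs = (keep - 1L) * settings$dt_fs,
                 coords = coords[keep, , drop = FALSE],
                 velocities = vels[keep, , drop = FALSE],
                 energies = energies[keep, , drop = FALSE],
                 active = active[keep], uncertainty = unc[keep],
                 hops = hops_df, termination = termination,
                 masses = masses, settings = settings),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  nf <- length(x$times_fs)
  nh <- sum(x$hops$accepted)
  cat(sprintf("Trajectory: %d frames, %.2f fs, %d accepted hop(s) (%d frustrated), ended: %s\n",
              nf, x$times_fs[nf], nh, sum(x$hops$frustrated), x$termination))
  cat(sprintf("  final active state: S%d\n", x$active[nf] - 1L))
  invisible(x)
}

#' Total energy along a trajectory
#' @param trajectory a `trajectory`.
#' @return numeric vector of kinetic + active-surface potential energy
#'   (hartree) per frame.
#' @export
total_energy <- function(trajectory) {
  ke <- 0.5 * as.numeric(trajectory$velocities^2 %*% trajectory$masses)
  pe <- trajectory$energies[cbind(seq_along(trajectory$active),
                                  trajectory$active)]
  ke + pe
}

#' Propagate an ensemble of trajectories
#'
#' Per-trajectory seeds are `base_seed + index - 1`, so results are
#' identical regardless of execution order; failed trajectories are
#' carried in the output with their termination reason.
#'
#' @param potential any multi-state potential.
#' @param initials non-empty list of initial conditions
#'   (`coords`, `velocities`, `state`).
#' @param settings a [propagation_settings()].
#' @param base_seed base RNG seed.
#' @param masses,fidelity passed to [propagate()].
#' @return list of class `trajectory_ensemble`.
#' @export
run_ensemble <- function(potential, initials, settings = propagation_settings(),
                         base_seed = 1, masses = NULL, fidelity = NULL) {
  stop_if(length(initials) == 0, "no initial conditions supplied")
  out <- vector("list", length(initials))
  for (i in seq_along(initials)) {
    st <- settings
    st$seed <- base_seed + i - 1L
    out[[i]] <- propagate(potential, initials[[i]], st, masses = masses,
                          fidelity = fidelity)
  }
  structure(out, class = "trajectory_ensemble")
}

#' Termination tally of a trajectory ensemble
#' @param ensemble a `trajectory_ensemble`.
#' @return data frame with counts and percentages per termination reason.
#' @export
termination_tally <- function(ensemble) {
  reasons <- vapply(ensemble, function(tr) tr$termination, "")
  tab <- table(factor(reasons, levels = c("completed", "uncertainty_exceeded",
                                          "distorted", "numeric_failure")))
  data.frame(termination = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(ensemble))
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d trajectories\n", length(x)))
  t <- termination_tally(x)
  removed <- sum(t$n[t$termination != "completed"])
  for (i in seq_len(nrow(t))) if (t$n[i] > 0)
    cat(sprintf("  %s: %d (%.1f%%)\n", t$termination[i], t$n[i], t$percent[i]))
  cat(sprintf("  removed from analysis: %d (%.1f%%)\n", removed,
              100 * removed / length(x)))
  invisible(x)
}
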