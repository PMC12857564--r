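#' Penalty settings for conical-intersection optimization
#'
#' @param sigma0 initial penalty weight (dimensionless).
#' @param sigma_factor multiplicative growth per outer cycle (>= 1).
#' @param alpha smoothing parameter (hartree, > 0).
#' @param max_cycles maximum outer cycles.
#' @param gap_tol convergence threshold on the energy gap (hartree).
#' @param grad_tol convergence threshold on the objective gradient norm
#'   (hartree/bohr).
#' @param inner_maxit iteration cap of the inner quasi-Newton minimizer.
#' @return list of class `penalty_settings`.
#' @export
penalty_settings <- function(sigma0 = 3.5, sigma_factor = 2, alpha = 0.02,
                             max_cycles = 12, gap_tol = 1e-3,
                             grad_tol = 1e-4, inner_maxit = 200) {
  stop_if(alpha <= 0, "alpha must be positive")
  stop_if(sigma_factor < 1, "sigma schedule must be non-decreasing")
  structure(list(sigma0 = sigma0, sigma_factor = sigma_factor, alpha = alpha,
                 max_cycles = max_cycles, gap_tol = gap_tol,
                 grad_tol = grad_tol, inner_maxit = inner_maxit),
            class = "penalty_settings")
}

#' Minimum-energy conical intersection by penalty minimization
#'
#' Minimizes F(x) = (E_I + E_J)/2 + sigma * dE^2 / (dE + alpha) with
#' dE = E_J - E_I >= 0, using only energies and gradients of the two
#' states (no nonadiabatic coupling vectors -- the optimizer works on
#' gradient-free surrogates).  The penalty weight sigma grows by
#' `sigma_factor` each outer cycle until the gap and gradient criteria
#' are met; the inner minimizer is quasi-Newton (L-BFGS) on Cartesian
#' coordinates with analytic objective gradients.  Deterministic for a
#' fixed start and settings.
#'
#' @param potential any multi-state potential.
#' @param x0 starting geometry (bohr).
#' @param states integer pair (I, J), usually adjacent.
#' @param settings a [penalty_settings()].
#' @param fidelity fidelity tag for surrogate potentials.
#' @return list of class `meci_result`: `geometry`, `energies`, `gap`,
#'   `converged`, `cycles`, `sigma_final`, `objective_trace`.
#' @export
optimize_meci <- function(potential, x0, states = c(1, 2),
                          settings = penalty_settings(), fidelity = NULL) {
  x0 <- as.numeric(x0)
  stop_if(any(!is.finite(x0)), "non-finite start geometry")
  I <- states[1]; J <- states[2]
  evalf <- make_evaluator(potential, fidelity)
  penalty <- function(de, sigma) sigma * de^2 / (de + settings$alpha)
  dpenalty <- function(de, sigma)
    sigma * (de^2 + 2 * settings$alpha * de) / (de + settings$alpha)^2

  obj <- function(x, sigma) {
    ap <- evalf(x)
    de <- ap$energies[J] - ap$energies[I]
    (ap$energies[I] + ap$energies[J]) / 2 + penalty(de, sigma)
  }
  grad <- function(x, sigma) {
    ap <- evalf(x)
    de <- ap$energies[J] - ap$energies[I]
    gI <- ap$gradients[I, ]; gJ <- ap$gradients[J, ]
    (gI + gJ) / 2 + dpenalty(de, sigma) * (gJ - gI)
  }

  x <- x0
  sigma <- settings$sigma0
  converged <- FALSE
  trace <- numeric(0)
  cycles <- 0L
  for (cycle in seq_len(settings$max_cycles)) {
    cycles <- cycle
    f_before <- obj(x, sigma)
    opt <- stats::optim(x, fn = obj, gr = grad, sigma = sigma,
                        method = "L-BFGS-B",
                        control = list(maxit = settings$inner_maxit,
                                       factr = 1e4))
    ## inner minimization never increases the objective at fixed sigma
    if (opt$value <= f_before + 1e-12) x <- opt$par
    trace <- c(trace, opt$value)
    ap <- evalf(x)
    de <- ap$energies[J] - ap$energies[I]
    gn <- sqrt(sum(grad(x, sigma)^2))
    if (de <= settings$gap_tol && gn <= settings$grad_tol) {
      converged <- TRUE
      break
    }
    sigma <- sigma * settings$sigma_factor
  }
  ap <- evalf(x)
  structure(list(geometry = x, energies = ap$energies,
                 gap = ap$energies[J] - ap$energies[I],
                 converged = converged, cycles = cycles,
                 sigma_final = sigma, objective_trace = trace,
                 states = states),
            class = "meci_result")
}

#' @export
print.meci_result <- function(x, ...) {
  cat(sprintf("MECI optimization (states %d/%d): %s after %d cycle(s)\n",
              x$states[1], x$states[2],
              if (x$converged) "converged" else "NOT converged", x$cycles))
  cat("  geometry (bohr):", paste(sprintf("%.6f", x$geometry), collapse = " "), "\n")
  cat(sprintf("  gap: %.3e hartree; E = %s\n", x$gap,
              paste(sprintf("%.6f", x$energies), collapse = " ")))
  invisible(x)
}
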