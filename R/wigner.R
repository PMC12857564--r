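#' Harmonic normal-mode specification
#'
#' @param equilibrium_coords equilibrium geometry (bohr).
#' @param frequencies per-mode angular frequencies (atomic units, > 0).
#' @param mode_vectors matrix (n_coords x n_modes) of mass-weighted
#'   displacement directions, orthonormal columns.
#' @param masses per-coordinate masses (a.u.).
#' @return object of class `normal_mode_spec`.
#' @export
normal_mode_spec <- function(equilibrium_coords, frequencies, mode_vectors,
                             masses) {
  nc <- length(equilibrium_coords)
  mode_vectors <- as.matrix(mode_vectors)
  stop_if(nrow(mode_vectors) != nc, "mode vectors must have n_coords rows")
  stop_if(ncol(mode_vectors) != length(frequencies),
          "need one frequency per mode")
  stop_if(length(masses) != nc, "need one mass per coordinate")
  bad <- which(frequencies <= 0)
  stop_if(length(bad) > 0,
          sprintf("non-positive frequency for mode(s): %s",
                  paste(bad, collapse = ", ")))
  gram <- crossprod(mode_vectors)
  stop_if(!isTRUE(all.equal(gram, diag(ncol(mode_vectors)), tolerance = 1e-8)),
          "mode vectors must be orthonormal (mass-weighted)")
  structure(list(equilibrium_coords = as.numeric(equilibrium_coords),
                 frequencies = as.numeric(frequencies),
                 mode_vectors = mode_vectors, masses = as.numeric(masses)),
            class = "normal_mode_spec")
}

#' Wigner sampling of the ground vibrational state
#'
#' Draws positions and momenta per mode independently from the harmonic
#' ground-state Wigner distribution: Gaussians with Var(q) = hbar/(2 w)
#' and Var(p) = hbar w / 2 in mass-weighted coordinates (0 K; no thermal
#' excitation).  Cartesian positions and velocities are recovered through
#' the mode vectors and masses.
#'
#' @param spec a [normal_mode_spec()].
#' @param n number of samples (> 0).
#' @param seed RNG seed; fixed seed gives identical samples.
#' @return list of `n` samples, each a list with `coords` (bohr) and
#'   `velocities` (bohr per atomic time).
#' @export
wigner_sample <- function(spec, n, seed) {
  stopifnot(inherits(spec, "normal_mode_spec"))
  stop_if(n <= 0, "n must be positive")
  set.seed(seed)
  nm <- length(spec$frequencies)
  sd_q <- sqrt(1 / (2 * spec$frequencies))
  sd_p <- sqrt(spec$frequencies / 2)
  q <- matrix(stats::rnorm(n * nm), n, nm) * rep(sd_q, each = n)
  p <- matrix(stats::rnorm(n * nm), n, nm) * rep(sd_p, each = n)
  inv_sqrt_m <- 1 / sqrt(spec$masses)
  lapply(seq_len(n), function(i) {
    dx <- inv_sqrt_m * as.numeric(spec$mode_vectors %*% q[i, ])
    v <- inv_sqrt_m * as.numeric(spec$mode_vectors %*% p[i, ])
    list(coords = spec$equilibrium_coords + dx, velocities = v)
  })
}

#' Filter sampled initial conditions to an excitation window
#'
#' Keeps samples whose vertical excitation energy E_k - E_j (evaluated
#' on `potential`) lies inside `window`; order is preserved.  An empty
#' result is returned with a warning, not an error.
#'
#' @param samples list of samples from [wigner_sample()].
#' @param potential any multi-state potential.
#' @param fidelity fidelity tag for surrogate potentials.
#' @param window numeric length-2 interval (hartree), lower < upper.
#' @param target_gap integer pair (j, k) of states defining the gap
#'   (1-based, ground state = 1).
#' @return the filtered list of samples.
#' @export
excitation_window_filter <- function(samples, potential, fidelity = NULL,
                                     window, target_gap = c(1, 2)) {
  stop_if(length(window) != 2 || window[1] >= window[2],
          "window must be (lower, upper) with lower < upper")
  keep <- vapply(samples, function(s) {
    ap <- eval_potential(potential, s$coords, fidelity = fidelity,
                         gradients = FALSE)
    gap <- ap$energies[target_gap[2]] - ap$energies[target_gap[1]]
    gap >= window[1] && gap <= window[2]
  }, TRUE)
  out <- samples[keep]
  if (length(out) == 0)
    warning("excitation window excludes every sample; returning empty list")
  out
}
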