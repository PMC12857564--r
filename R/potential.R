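#' Evaluate a multi-state potential at a geometry
#'
#' Common contract shared by analytic diabatic models, trained
#' surrogates and surrogate ensembles: coordinates (plus a fidelity tag
#' for multi-fidelity surrogates) map to ascending adiabatic energies,
#' optionally with gradients and a per-state uncertainty.
#'
#' @param potential a `diabatic_model`, `surrogate_model` or
#'   `surrogate_ensemble`.
#' @param x coordinate vector (bohr).
#' @param fidelity fidelity tag (ignored by analytic models).
#' @param gradients compute per-state gradients?
#' @param ... passed to methods.
#' @return an [adiabatic_point()].
#' @export
eval_potential <- function(potential, x, fidelity = NULL, gradients = TRUE, ...) {
  UseMethod("eval_potential")
}

#' @export
eval_potential.diabatic_model <- function(potential, x, fidelity = NULL,
                                          gradients = TRUE, ...) {
  evaluate_adiabatic(potential, x, with_gradients = gradients)
}

#' Number of electronic states of a potential
#' @param potential a potential object.
#' @return integer count.
#' @export
n_states <- function(potential) UseMethod("n_states")

#' @export
n_states.diabatic_model <- function(potential) potential$n_states

#' Number of nuclear coordinates of a potential
#' @param potential a potential object.
#' @return integer count.
#' @export
n_coords <- function(potential) UseMethod("n_coords")

#' @export
n_coords.diabatic_model <- function(potential) potential$n_coords

## internal: resolve a fast single-point evaluator once, so the
## propagation inner loop avoids repeated S3 dispatch and container
## construction.  The returned closure yields a plain list with
## `energies` (ascending), `gradients` (n_states x n_coords) and
## `uncertainty`; it is equivalent to eval_potential() up to the
## omitted gap matrix and flags.
make_evaluator <- function(potential, fidelity) {
  if (inherits(potential, "diabatic_model")) {
    vfun <- potential$vfun; dvfun <- potential$dvfun
    par <- potential$params
    S <- potential$n_states; nc <- potential$n_coords
    zero_unc <- rep(0, S)
    function(x) {
      eg <- eigen(vfun(x, par), symmetric = TRUE)
      ord <- S:1                       # symmetric eigen() is decreasing
      u <- eg$vectors[, ord, drop = FALSE]
      dv <- dvfun(x, par)
      grads <- matrix(0, S, nc)
      for (d in seq_len(nc)) grads[, d] <- colSums(u * (dv[, , d] %*% u))
      list(energies = eg$values[ord], gradients = grads,
           uncertainty = zero_unc)
    }
  } else if (inherits(potential, "surrogate_model")) {
    fast_surrogate_evaluator(potential, fidelity)
  } else if (inherits(potential, "surrogate_ensemble")) {
    evs <- lapply(potential$members, fast_surrogate_evaluator, fidelity = fidelity)
    M <- length(evs)
    S <- potential$members[[1]]$n_states
    function(x) {
      p <- evs[[1]](x)
      e_all <- matrix(0, S, M)
      e_all[, 1] <- p$energies
      g <- p$gradients
      if (M > 1) for (m in 2:M) {
        pm <- evs[[m]](x)
        e_all[, m] <- pm$energies
        g <- g + pm$gradients
      }
      e <- rowMeans(e_all)
      unc <- if (M > 1) sqrt(rowSums((e_all - e)^2) / (M - 1)) else rep(0, S)
      ord <- order(e)
      list(energies = e[ord], gradients = (g / M)[ord, , drop = FALSE],
           uncertainty = unc[ord])
    }
  } else {
    function(x) eval_potential(potential, x, fidelity = fidelity,
                               gradients = TRUE)
  }
}

## lean closure for one surrogate at one fidelity (two hidden layers are
## unrolled; other depths fall back to the generic forward pass)
fast_surrogate_evaluator <- function(model, fidelity) {
  fidelity <- fidelity %||% model$fidelities[1]
  fd <- if (is.list(fidelity)) fidelity else
    fidelity_descriptor(fidelity, model$fidelities)
  nc <- model$n_coords; S <- model$n_states
  xc <- model$x_center; xs <- model$x_scale
  ec <- model$e_center; es <- model$e_scale
  oh <- fd$one_hot
  zero_unc <- rep(0, S)
  par <- model$par
  if (length(model$hidden) != 2) {
    return(function(x) {
      u <- matrix(c((x - xc) / xs, oh), ncol = 1)
      fw <- nn_forward(par, u, tangents = TRUE, n_tan = nc)
      e <- as.numeric(es * fw$E + ec)
      grads <- matrix(0, S, nc)
      for (d in seq_len(nc)) grads[, d] <- (es / xs[d]) * fw$G[[d]]
      ord <- order(e)
      list(energies = e[ord], gradients = grads[ord, , drop = FALSE],
           uncertainty = zero_unc)
    })
  }
  W1 <- par$W[[1]]; b1 <- par$b[[1]]
  W2 <- par$W[[2]]; b2 <- par$b[[2]]
  W3 <- par$Wout; b3 <- par$bout
  W1c <- W1[, seq_len(nc), drop = FALSE]   # tangent seed columns
  gscale <- es / xs
  function(x) {
    a1 <- tanh(W1 %*% c((x - xc) / xs, oh) + b1)
    a2 <- tanh(W2 %*% a1 + b2)
    e <- as.numeric(es * (W3 %*% a2 + b3) + ec)
    t1 <- 1 - a1 * a1
    t2 <- 1 - a2 * a2
    a1d <- (t1 %*% rep(1, nc)) * W1c          # h1 x nc tangents
    a2d <- (t2 %*% rep(1, nc)) * (W2 %*% a1d)
    grads <- t(t(W3 %*% a2d) * gscale)        # S x nc
    ord <- order(e)
    list(energies = e[ord], gradients = grads[ord, , drop = FALSE],
         uncertainty = zero_unc)
  }
}
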