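#' Multi-state, multi-fidelity surrogate potentials
#'
#' The surrogate is a plain feed-forward network (tanh hidden layers, one
#' output head per electronic state) on the nuclear coordinates with a
#' one-hot fidelity descriptor concatenated to the input.  It is fully
#' differentiable: energy gradients (and hence forces) are computed by
#' analytic forward-mode differentiation of the network, never by finite
#' differences.  Training minimizes a composite loss of energy, adjacent
#' state-gap and (where reference gradients exist) energy-gradient terms,
#' so a model trained on energies alone still yields dynamics-quality
#' forces -- the mechanism this package exists to exercise.
#'
#' @name surrogate
NULL

#' Fidelity descriptor
#'
#' @param name fidelity tag.
#' @param fidelities character vector of all configured tags.
#' @return list with `name` and the one-hot `one_hot` vector.
#' @export
fidelity_descriptor <- function(name, fidelities) {
  i <- match(name, fidelities)
  stop_if(is.na(i), sprintf("unknown fidelity '%s'; configured: %s",
                            name, paste(fidelities, collapse = ", ")))
  oh <- rep(0, length(fidelities)); oh[i] <- 1
  list(name = name, one_hot = oh)
}

#' Loss weights for surrogate training
#'
#' Defaults follow common practice for multi-state potential fitting:
#' 1, 1 and 0.1 for energies, gaps and energy gradients.
#'
#' @param w_energy weight of the squared energy error term.
#' @param w_gap weight of the adjacent-gap squared error term.
#' @param w_force weight of the gradient (force) term; ignored for
#'   records that carry no reference gradients.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(w_energy = 1, w_gap = 1, w_force = 0.1) {
  stop_if(any(c(w_energy, w_gap, w_force) < 0), "loss weights must be >= 0")
  structure(list(w_energy = w_energy, w_gap = w_gap, w_force = w_force),
            class = "loss_weights")
}

#' Training schedule
#'
#' Adam optimization with a reduce-on-plateau learning-rate schedule:
#' after `plateau_patience` epochs without validation improvement the
#' learning rate is multiplied by `lr_factor`; training stops once it
#' falls below `stop_lr` (or at `max_epochs`, a safety cap).
#'
#' @param initial_lr initial learning rate.
#' @param plateau_patience epochs without improvement before a reduction.
#' @param lr_factor multiplicative reduction factor in (0, 1).
#' @param stop_lr terminate when the learning rate drops below this.
#' @param batch_size minibatch size.
#' @param max_epochs hard cap on epochs.
#' @param seed RNG seed controlling the validation split and shuffling.
#' @return list of class `training_schedule`.
#' @export
training_schedule <- function(initial_lr = 0.001, plateau_patience = 50,
                              lr_factor = 0.5, stop_lr = 1e-5,
                              batch_size = 32, max_epochs = 4000, seed = 1) {
  stop_if(lr_factor <= 0 || lr_factor >= 1, "lr_factor must be in (0, 1)")
  stop_if(stop_lr >= initial_lr, "stop_lr must be below initial_lr")
  stop_if(batch_size < 1, "batch_size must be positive")
  structure(list(initial_lr = initial_lr, plateau_patience = plateau_patience,
                 lr_factor = lr_factor, stop_lr = stop_lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = seed),
            class = "training_schedule")
}

## ---------------------------------------------------------------------------
## parameter packing

nn_shapes <- function(din, hidden, s) {
  sizes <- c(din, hidden)
  shp <- list(W = list(), b = list())
  L <- length(hidden)
  for (l in seq_len(L)) {
    shp$W[[l]] <- c(hidden[l], sizes[l])
    shp$b[[l]] <- hidden[l]
  }
  shp$Wout <- c(s, sizes[L + 1])
  shp$bout <- s
  shp
}

nn_npar <- function(shp) {
  n <- prod(shp$Wout) + shp$bout
  for (l in seq_along(shp$W)) n <- n + prod(shp$W[[l]]) + shp$b[[l]]
  n
}

nn_unpack <- function(theta, shp) {
  pos <- 0L
  take <- function(n) {
    v <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    v
  }
  L <- length(shp$W)
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(take(prod(shp$W[[l]])), shp$W[[l]][1], shp$W[[l]][2])
    b[[l]] <- take(shp$b[[l]])
  }
  Wout <- matrix(take(prod(shp$Wout)), shp$Wout[1], shp$Wout[2])
  bout <- take(shp$bout)
  list(W = W, b = b, Wout = Wout, bout = bout)
}

nn_pack <- function(par) {
  out <- numeric(0)
  for (l in seq_along(par$W)) out <- c(out, as.numeric(par$W[[l]]), par$b[[l]])
  c(out, as.numeric(par$Wout), par$bout)
}

nn_init <- function(din, hidden, s, seed) {
  set.seed(seed)
  sizes <- c(din, hidden)
  L <- length(hidden)
  par <- list(W = vector("list", L), b = vector("list", L))
  for (l in seq_len(L)) {
    sd0 <- sqrt(2 / (sizes[l] + sizes[l + 1]))
    par$W[[l]] <- matrix(stats::rnorm(sizes[l + 1] * sizes[l], 0, sd0),
                         sizes[l + 1], sizes[l])
    par$b[[l]] <- rep(0, sizes[l + 1])
  }
  sd0 <- sqrt(2 / (sizes[L + 1] + s))
  par$Wout <- matrix(stats::rnorm(s * sizes[L + 1], 0, sd0), s, sizes[L + 1])
  par$bout <- rep(0, s)
  par
}

## forward pass; U is din x B.  Returns raw (unscaled) energies S x B and,
## when tangents is TRUE, the raw jacobians wrt the first n_tan inputs.
nn_forward <- function(par, U, tangents = FALSE, n_tan = 0L) {
  L <- length(par$W)
  B <- ncol(U)
  A <- vector("list", L)
  prev <- U
  for (l in seq_len(L)) {
    A[[l]] <- tanh(par$W[[l]] %*% prev + par$b[[l]])
    prev <- A[[l]]
  }
  E <- par$Wout %*% prev + par$bout
  out <- list(E = E, A = A)
  if (tangents && n_tan > 0L) {
    Zdot <- vector("list", n_tan)   # Zdot[[d]][[l]]
    Adot <- vector("list", n_tan)
    G <- vector("list", n_tan)      # raw dE/du_d, S x B
    for (d in seq_len(n_tan)) {
      Zdot[[d]] <- vector("list", L)
      Adot[[d]] <- vector("list", L)
      if (L == 0L) {
        G[[d]] <- matrix(par$Wout[, d], nrow(par$Wout), B)
        next
      }
      zd <- matrix(par$W[[1]][, d], nrow(par$W[[1]]), B)
      Zdot[[d]][[1]] <- zd
      Adot[[d]][[1]] <- (1 - A[[1]]^2) * zd
      if (L > 1) for (l in 2:L) {
        zd <- par$W[[l]] %*% Adot[[d]][[l - 1]]
        Zdot[[d]][[l]] <- zd
        Adot[[d]][[l]] <- (1 - A[[l]]^2) * zd
      }
      G[[d]] <- par$Wout %*% Adot[[d]][[L]]
    }
    out$Zdot <- Zdot; out$Adot <- Adot; out$G <- G
  }
  out
}

## reverse pass through the primal + tangent graph.
## Ebar: S x B adjoint of raw energies; Gbar: list over tangent dims of
## S x B adjoints of raw jacobians (may be NULL).  Returns gradient as a
## par-shaped list.
nn_backward <- function(par, U, fw, Ebar, Gbar = NULL) {
  L <- length(par$W)
  nt <- length(Gbar %||% list())
  g <- list(W = vector("list", L), b = vector("list", L))
  AL <- if (L > 0) fw$A[[L]] else U
  gWout <- Ebar %*% t(AL)
  gbout <- rowSums(Ebar)
  if (nt > 0 && L > 0) {
    for (d in seq_len(nt)) gWout <- gWout + Gbar[[d]] %*% t(fw$Adot[[d]][[L]])
  } else if (nt > 0 && L == 0) {
    for (d in seq_len(nt)) gWout[, d] <- gWout[, d] + rowSums(Gbar[[d]])
  }
  if (L > 0) {
    Abar <- t(par$Wout) %*% Ebar
    Adotbar <- if (nt > 0) lapply(Gbar, function(gb) t(par$Wout) %*% gb) else NULL
    for (l in L:1) {
      Al <- fw$A[[l]]
      tl <- 1 - Al^2
      Zdotbar <- NULL
      if (nt > 0) {
        Zdotbar <- vector("list", nt)
        for (d in seq_len(nt)) {
          Zdotbar[[d]] <- tl * Adotbar[[d]]
          Abar <- Abar - 2 * Al * fw$Zdot[[d]][[l]] * Adotbar[[d]]
        }
      }
      Zbar <- tl * Abar
      prev <- if (l > 1) fw$A[[l - 1]] else U
      gW <- Zbar %*% t(prev)
      if (nt > 0) {
        if (l > 1) {
          for (d in seq_len(nt)) gW <- gW + Zdotbar[[d]] %*% t(fw$Adot[[d]][[l - 1]])
        } else {
          for (d in seq_len(nt)) gW[, d] <- gW[, d] + rowSums(Zdotbar[[d]])
        }
      }
      g$W[[l]] <- gW
      g$b[[l]] <- rowSums(Zbar)
      if (l > 1) {
        Abar <- t(par$W[[l]]) %*% Zbar
        if (nt > 0) Adotbar <- lapply(Zdotbar, function(zb) t(par$W[[l]]) %*% zb)
      }
    }
  }
  g$Wout <- gWout
  g$bout <- gbout
  g
}

## ---------------------------------------------------------------------------
## model object

#' Build an (untrained) surrogate potential
#'
#' @param n_coords number of nuclear coordinates.
#' @param n_states number of electronic states (>= 2).
#' @param fidelities character vector of fidelity tags (>= 1).
#' @param hidden integer vector of hidden-layer widths.
#' @param seed RNG seed for weight initialization; identical seeds give
#'   identical initial parameters.
#' @return object of class `surrogate_model`.
#' @export
build_surrogate <- function(n_coords, n_states, fidelities,
                            hidden = c(32, 32), seed = 1) {
  stop_if(n_states < 2, "need at least 2 electronic states")
  stop_if(length(fidelities) < 1, "need at least one fidelity tag")
  hidden <- as.integer(hidden)
  if (length(hidden) == 0 && n_coords > 1)
    warning("no hidden layers with multi-dimensional input: the surrogate is linear and will underfit")
  din <- n_coords + length(fidelities)
  shp <- nn_shapes(din, hidden, n_states)
  par <- nn_init(din, hidden, n_states, seed)
  structure(list(n_coords = as.integer(n_coords),
                 n_states = as.integer(n_states),
                 fidelities = as.character(fidelities), hidden = hidden,
                 shapes = shp, par = par, seed = seed,
                 x_center = rep(0, n_coords), x_scale = rep(1, n_coords),
                 e_center = rep(0, n_states), e_scale = 1,
                 trained = FALSE, log = NULL),
            class = "surrogate_model")
}

#' @export
n_states.surrogate_model <- function(potential) potential$n_states

#' @export
n_coords.surrogate_model <- function(potential) potential$n_coords

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("Surrogate potential: %d coordinate(s) -> %d state energies\n",
              x$n_coords, x$n_states))
  cat("  hidden layers:", if (length(x$hidden)) paste(x$hidden, collapse = "-") else "(none)", "\n")
  cat("  fidelities:", paste(x$fidelities, collapse = ", "), "\n")
  cat("  parameters:", nn_npar(x$shapes), "\n")
  if (x$trained) {
    n <- nrow(x$log)
    cat(sprintf("  trained: %d epochs, final validation loss %.3e\n",
                n, x$log$val_loss[n]))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
coef.surrogate_model <- function(object, ...) nn_pack(object$par)

## build the din x B input matrix for a set of records
surrogate_inputs <- function(model, coords_mat, fid_names) {
  B <- nrow(coords_mat)
  xs <- t((t(coords_mat) - model$x_center) / model$x_scale)  # B x nc
  oh <- matrix(0, B, length(model$fidelities))
  idx <- match(fid_names, model$fidelities)
  stop_if(anyNA(idx), sprintf("unknown fidelity tag; configured: %s",
                              paste(model$fidelities, collapse = ", ")))
  oh[cbind(seq_len(B), idx)] <- 1
  t(cbind(xs, oh))
}

## assemble label matrices from a labeled_dataset
surrogate_labels <- function(model, dataset) {
  B <- length(dataset)
  S <- model$n_states; nc <- model$n_coords
  coords <- t(matrix(vapply(dataset, function(r) as.numeric(r$coords),
                            numeric(nc)), nc, B))
  fids <- vapply(dataset, function(r) r$fidelity, "")
  E <- vapply(dataset, function(r) {
    stop_if(length(r$energies) != S, "record has wrong number of state energies")
    as.numeric(r$energies)
  }, numeric(S))
  E <- matrix(E, S, B)
  gmask <- vapply(dataset, function(r) !is.null(r$gradients), TRUE)
  Garr <- NULL
  if (any(gmask)) {
    Garr <- array(0, c(S, nc, B))
    for (i in which(gmask)) {
      gr <- dataset[[i]]$gradients
      stop_if(!all(dim(gr) == c(S, nc)),
              sprintf("record %d: gradient block must be %d x %d", i, S, nc))
      Garr[, , i] <- gr
    }
  }
  list(coords = coords, fids = fids, E = E, gmask = gmask, Garr = Garr)
}

## composite loss and its parameter gradient on a batch (already in
## matrix form).  Returns list(total, energy, gap, force, grad?).
nn_loss <- function(model, U, Eref, gmask, Garr, w, with_grad = FALSE) {
  S <- model$n_states; nc <- model$n_coords
  B <- ncol(U)
  need_tan <- w$w_force > 0 && any(gmask)
  fw <- nn_forward(model$par, U, tangents = need_tan, n_tan = if (need_tan) nc else 0L)
  E <- model$e_scale * fw$E + model$e_center          # S x B, hartree
  Eres <- E - Eref
  L_E <- sum(Eres^2) / B
  ## adjacent gaps
  if (S > 1) {
    gap_ml <- E[-1, , drop = FALSE] - E[-S, , drop = FALSE]
    gap_ref <- Eref[-1, , drop = FALSE] - Eref[-S, , drop = FALSE]
    gres <- gap_ml - gap_ref
    L_gap <- sum(gres^2) / B
  } else { gres <- NULL; L_gap <- 0 }
  L_F <- 0
  Gres <- NULL
  Bg <- sum(gmask)
  if (need_tan) {
    Gres <- vector("list", nc)
    for (d in seq_len(nc)) {
      Gphys <- (model$e_scale / model$x_scale[d]) * fw$G[[d]]   # S x B
      rd <- Gphys - matrix(Garr[, d, ], S, B)
      rd[, !gmask] <- 0
      Gres[[d]] <- rd
      L_F <- L_F + sum(rd^2)
    }
    L_F <- L_F / Bg
  }
  total <- w$w_energy * L_E + w$w_gap * L_gap + w$w_force * L_F
  out <- list(total = total, energy = L_E, gap = L_gap, force = L_F)
  if (with_grad) {
    Ebar <- (2 * w$w_energy / B) * Eres
    if (!is.null(gres)) {
      gb <- (2 * w$w_gap / B) * gres
      Ebar[-1, ] <- Ebar[-1, , drop = FALSE] + gb
      Ebar[-S, ] <- Ebar[-S, , drop = FALSE] - gb
    }
    Ebar_raw <- model$e_scale * Ebar
    Gbar_raw <- NULL
    if (need_tan) {
      Gbar_raw <- vector("list", nc)
      for (d in seq_len(nc)) {
        Gbar_raw[[d]] <- (2 * w$w_force / Bg) *
          (model$e_scale / model$x_scale[d]) * Gres[[d]]
      }
    }
    out$grad <- nn_backward(model$par, U, fw, Ebar_raw, Gbar_raw)
  }
  out
}

#' Composite training loss on a batch of labeled configurations
#'
#' L = w_energy * mean ||E_ml - E_ref||^2
#'   + w_gap    * mean ||gap_ml - gap_ref||^2  (adjacent state pairs)
#'   + w_force  * mean ||grad_ml - grad_ref||^2,
#' where the force term runs only over records that carry reference
#' gradients and the model gradient is the analytic derivative of the
#' predicted energies (forces are their negatives; matching gradients
#' and matching forces are the same residual).
#'
#' @param batch a `labeled_dataset` (or plain list of records).
#' @param model a `surrogate_model`.
#' @param weights a [loss_weights()] object.
#' @return list with `total` and the `energy`, `gap`, `force` terms.
#' @export
surrogate_loss <- function(batch, model, weights = loss_weights()) {
  stop_if(length(batch) == 0, "empty batch")
  lab <- surrogate_labels(model, batch)
  U <- surrogate_inputs(model, lab$coords, lab$fids)
  res <- nn_loss(model, U, lab$E, lab$gmask, lab$Garr, weights)
  res[c("total", "energy", "gap", "force")]
}

## Adam state helpers operating on flat vectors
adam_step <- function(theta, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  st$theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  st
}

#' Train a surrogate potential
#'
#' Fits the network to a labeled dataset by Adam with a
#' reduce-on-plateau learning-rate schedule, holding out a random
#' validation fraction; the parameters with the best validation loss are
#' returned.  Fully reproducible for a fixed `schedule$seed`.
#'
#' @param model a `surrogate_model` from [build_surrogate()].
#' @param dataset a `labeled_dataset` covering every configured fidelity.
#' @param weights a [loss_weights()] object.
#' @param schedule a [training_schedule()] object.
#' @param validation_fraction fraction of records held out (default 0.1).
#' @return the trained `surrogate_model`, with a `log` data frame
#'   (epoch, lr, train_loss, val_loss).
#' @export
train_surrogate <- function(model, dataset, weights = loss_weights(),
                            schedule = training_schedule(),
                            validation_fraction = 0.1) {
  stopifnot(inherits(model, "surrogate_model"))
  lab <- surrogate_labels(model, dataset)
  missing_fid <- setdiff(model$fidelities, unique(lab$fids))
  stop_if(length(missing_fid) > 0,
          sprintf("dataset does not cover fidelity(ies): %s",
                  paste(missing_fid, collapse = ", ")))
  N <- length(dataset)
  ## input/output standardization from the training data (fixed constants
  ## of the fitted model thereafter)
  model$x_center <- colMeans(lab$coords)
  xs <- apply(lab$coords, 2, stats::sd)
  model$x_scale <- ifelse(xs > 0, xs, 1)
  model$e_center <- rowMeans(lab$E)
  es <- stats::sd(as.numeric(lab$E - model$e_center))
  model$e_scale <- if (is.finite(es) && es > 0) es else 1
  U <- surrogate_inputs(model, lab$coords, lab$fids)

  set.seed(schedule$seed)
  n_val <- max(1L, round(validation_fraction * N))
  stop_if(n_val >= N, "validation split leaves no training data")
  val_idx <- sample.int(N, n_val)
  tr_idx <- setdiff(seq_len(N), val_idx)

  theta <- nn_pack(model$par)
  st <- list(theta = theta, m = numeric(length(theta)),
             v = numeric(length(theta)), t = 0)
  lr <- schedule$initial_lr
  best_val <- Inf; best_theta <- theta; wait <- 0L
  log_epoch <- integer(0); log_lr <- log_tr <- log_val <- numeric(0)
  bs <- schedule$batch_size
  Uv <- U[, val_idx, drop = FALSE]
  Ev <- lab$E[, val_idx, drop = FALSE]
  gv <- lab$gmask[val_idx]
  Gv <- if (!is.null(lab$Garr)) lab$Garr[, , val_idx, drop = FALSE] else NULL
  epoch <- 0L
  while (lr >= schedule$stop_lr && epoch < schedule$max_epochs) {
    epoch <- epoch + 1L
    perm <- sample(tr_idx)
    tr_loss <- 0; nb <- 0L
    for (start in seq(1L, length(perm), by = bs)) {
      idx <- perm[start:min(start + bs - 1L, length(perm))]
      ## skip degenerate 1-record tail batches only if they would break sd
      Ub <- U[, idx, drop = FALSE]
      Eb <- lab$E[, idx, drop = FALSE]
      gb <- lab$gmask[idx]
      Gb <- if (!is.null(lab$Garr)) lab$Garr[, , idx, drop = FALSE] else NULL
      res <- nn_loss(model, Ub, Eb, gb, Gb, weights, with_grad = TRUE)
      if (!is.finite(res$total))
        stop(sprintf("NaN/Inf loss at epoch %d (lr %.2e); try a lower learning rate or cleaner labels", epoch, lr), call. = FALSE)
      st <- adam_step(st$theta, nn_pack(res$grad), st, lr)
      model$par <- nn_unpack(st$theta, model$shapes)
      tr_loss <- tr_loss + res$total; nb <- nb + 1L
    }
    vres <- nn_loss(model, Uv, Ev, gv, Gv, weights)
    log_epoch <- c(log_epoch, epoch); log_lr <- c(log_lr, lr)
    log_tr <- c(log_tr, tr_loss / nb); log_val <- c(log_val, vres$total)
    if (vres$total < best_val * (1 - 1e-6)) {
      best_val <- vres$total; best_theta <- st$theta; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= schedule$plateau_patience) { lr <- lr * schedule$lr_factor; wait <- 0L }
    }
  }
  model$par <- nn_unpack(best_theta, model$shapes)
  model$trained <- TRUE
  model$log <- data.frame(epoch = log_epoch, lr = log_lr,
                          train_loss = log_tr, val_loss = log_val)
  model$training <- list(weights = weights, schedule = schedule,
                         n_train = length(tr_idx), n_val = n_val,
                         best_val = best_val)
  model
}

#' @export
summary.surrogate_model <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat(sprintf("  training records: %d (+%d validation)\n",
                object$training$n_train, object$training$n_val))
    cat(sprintf("  best validation loss: %.3e\n", object$training$best_val))
  }
  invisible(object)
}

#' @export
plot.surrogate_model <- function(x, ...) {
  stop_if(!x$trained, "model is untrained; nothing to plot")
  graphics::plot(x$log$epoch, x$log$val_loss, type = "l", log = "y",
                 xlab = "epoch", ylab = "loss", col = "firebrick", ...)
  graphics::lines(x$log$epoch, x$log$train_loss, col = "grey40", lty = 2)
  graphics::legend("topright", c("validation", "training"),
                   col = c("firebrick", "grey40"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Predict adiabatic energies (and forces) with a surrogate
#'
#' Forces, when requested, are exactly minus the analytic derivative of
#' the predicted energies (forward-mode differentiation of the network).
#' Raw network outputs are re-sorted ascending; `reordered` in the result
#' records whether the raw ordering was violated.
#'
#' @param object a trained `surrogate_model`.
#' @param x coordinate vector (bohr).
#' @param fidelity fidelity tag (defaults to the first configured one).
#' @param with_forces compute gradients/forces?
#' @param ... unused.
#' @return an [adiabatic_point()] (its `gradients` are dE/dx; forces are
#'   their negatives).
#' @export
predict.surrogate_model <- function(object, x, fidelity = NULL,
                                    with_forces = FALSE, ...) {
  x <- as.numeric(x)
  stop_if(any(!is.finite(x)), "non-finite coordinates")
  stop_if(length(x) != object$n_coords, "x has wrong length")
  fidelity <- fidelity %||% object$fidelities[1]
  fd <- if (is.list(fidelity)) fidelity else fidelity_descriptor(fidelity, object$fidelities)
  u <- matrix(c((x - object$x_center) / object$x_scale, fd$one_hot), ncol = 1)
  nc <- object$n_coords
  fw <- nn_forward(object$par, u, tangents = with_forces, n_tan = if (with_forces) nc else 0L)
  e <- as.numeric(object$e_scale * fw$E + object$e_center)
  grads <- NULL
  if (with_forces) {
    grads <- matrix(0, object$n_states, nc)
    for (d in seq_len(nc))
      grads[, d] <- object$e_scale / object$x_scale[d] * as.numeric(fw$G[[d]])
  }
  adiabatic_point(e, grads, uncertainty = rep(0, object$n_states))
}

#' @export
eval_potential.surrogate_model <- function(potential, x, fidelity = NULL,
                                           gradients = TRUE, ...) {
  predict.surrogate_model(potential, x, fidelity = fidelity,
                          with_forces = gradients)
}

#' @export
fitted.surrogate_model <- function(object, dataset, ...) {
  stop_if(missing(dataset), "supply the dataset to evaluate on")
  lab <- surrogate_labels(object, dataset)
  U <- surrogate_inputs(object, lab$coords, lab$fids)
  fw <- nn_forward(object$par, U)
  t(object$e_scale * fw$E + object$e_center)
}

#' @export
residuals.surrogate_model <- function(object, dataset, ...) {
  lab <- surrogate_labels(object, dataset)
  fitted.surrogate_model(object, dataset) - t(lab$E)
}

## ---------------------------------------------------------------------------
## ensembles

#' Bundle trained surrogates into an ensemble
#'
#' @param members list of trained `surrogate_model`s sharing architecture.
#' @return object of class `surrogate_ensemble`.
#' @export
surrogate_ensemble <- function(members) {
  stop_if(length(members) == 0, "ensemble needs at least one member")
  for (m in members) stopifnot(inherits(m, "surrogate_model"))
  ref <- members[[1]]
  for (m in members[-1]) {
    stop_if(m$n_states != ref$n_states || m$n_coords != ref$n_coords ||
            !identical(m$fidelities, ref$fidelities),
            "ensemble members must share dimensions and fidelity tags")
  }
  if (length(members) == 1)
    warning("single-member ensemble: uncertainty is identically zero")
  structure(list(members = members), class = "surrogate_ensemble")
}

#' @export
n_states.surrogate_ensemble <- function(potential) potential$members[[1]]$n_states

#' @export
n_coords.surrogate_ensemble <- function(potential) potential$members[[1]]$n_coords

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("Surrogate ensemble: %d member(s)\n", length(x$members)))
  print(x$members[[1]])
  invisible(x)
}

#' Train an ensemble of surrogates with shared initial weights
#'
#' All members start from the same initialization (the weights of
#' `model`); diversity comes from the stochastic training streams
#' (validation split and minibatch shuffling differ per member seed).
#'
#' @param model untrained `surrogate_model` providing the shared init.
#' @param dataset,weights,schedule,validation_fraction as in
#'   [train_surrogate()].
#' @param n_members ensemble size.
#' @param member_seeds optional integer vector of per-member training
#'   seeds (defaults to `schedule$seed + 0:(n_members-1)`).
#' @return a `surrogate_ensemble`.
#' @export
train_surrogate_ensemble <- function(model, dataset, weights = loss_weights(),
                                     schedule = training_schedule(),
                                     n_members = 4, validation_fraction = 0.1,
                                     member_seeds = NULL) {
  member_seeds <- member_seeds %||% (schedule$seed + seq_len(n_members) - 1L)
  stop_if(length(member_seeds) != n_members, "need one seed per member")
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    sch <- schedule; sch$seed <- member_seeds[i]
    members[[i]] <- train_surrogate(model, dataset, weights, sch,
                                    validation_fraction)
  }
  ens <- surrogate_ensemble(members)
  ens$member_seeds <- member_seeds
  ens
}

#' Ensemble prediction with uncertainty
#'
#' Energies and gradients are member means; the per-state uncertainty is
#' the standard deviation of the member energy predictions (0 for a
#' single member).
#'
#' @param ensemble a `surrogate_ensemble`.
#' @param x coordinate vector (bohr).
#' @param fidelity fidelity tag.
#' @param with_forces compute mean gradients?
#' @return an [adiabatic_point()] whose `uncertainty` holds the per-state
#'   standard deviation (hartree).
#' @export
ensemble_predict <- function(ensemble, x, fidelity = NULL, with_forces = TRUE) {
  M <- length(ensemble$members)
  preds <- lapply(ensemble$members, predict, x = x, fidelity = fidelity,
                  with_forces = with_forces)
  Em <- vapply(preds, function(p) p$energies, numeric(length(preds[[1]]$energies)))
  Em <- matrix(Em, ncol = M)
  e_mean <- rowMeans(Em)
  unc <- if (M > 1) apply(Em, 1, stats::sd) else rep(0, nrow(Em))
  grads <- NULL
  if (with_forces) {
    grads <- Reduce(`+`, lapply(preds, function(p) p$gradients)) / M
  }
  adiabatic_point(e_mean, grads, uncertainty = unc)
}

#' @export
eval_potential.surrogate_ensemble <- function(potential, x, fidelity = NULL,
                                              gradients = TRUE, ...) {
  ensemble_predict(potential, x, fidelity = fidelity, with_forces = gradients)
}
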