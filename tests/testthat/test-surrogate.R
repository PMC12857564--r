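test_that("surrogate construction is deterministic and shape-correct", {
  s1 <- build_surrogate(2, 3, c("a", "b"), hidden = c(8, 8), seed = 4)
  s2 <- build_surrogate(2, 3, c("a", "b"), hidden = c(8, 8), seed = 4)
  expect_identical(coef(s1), coef(s2))
  s3 <- build_surrogate(2, 3, c("a", "b"), hidden = c(8, 8), seed = 5)
  expect_false(identical(coef(s1), coef(s3)))

  p <- predict(s1, c(0.3, -0.2), "a")
  expect_length(p$energies, 3)
  expect_true(all(is.finite(p$energies)))
  expect_error(predict(s1, c(0.3, -0.2), "nope"), "a, b")
  expect_warning(build_surrogate(2, 2, "a", hidden = integer(0), seed = 1),
                 "underfit")
})

test_that("predicted forces are analytic derivatives of predicted energies", {
  s <- build_surrogate(2, 3, c("hi", "lo"), hidden = c(10, 7), seed = 9)
  h <- 1e-5
  for (x0 in list(c(0.4, 0.1), c(-1.2, 0.8))) {
    p <- predict(s, x0, "lo", with_forces = TRUE)
    for (d in 1:2) {
      e <- c(0, 0); e[d] <- h
      fd <- (predict(s, x0 + e, "lo")$energies -
             predict(s, x0 - e, "lo")$energies) / (2 * h)
      expect_lt(max(abs(p$gradients[, d] - fd) / pmax(abs(fd), 1e-4)), 1e-5)
    }
  }
})

test_that("the composite loss matches its definition term by term", {
  ## pick a seed/point where the raw head order is already ascending, so
  ## the sorted prediction equals the per-head output the loss compares to
  x <- NA
  for (seed in 1:20) {
    s <- build_surrogate(1, 2, "f", hidden = c(6), seed = seed)
    for (cand in seq(-1, 1, by = 0.1)) {
      if (!predict(s, cand, "f")$reordered) { x <- cand; break }
    }
    if (!is.na(x)) break
  }
  expect_false(is.na(x))
  p <- predict(s, x, "f", with_forces = TRUE)
  ## a record matching the model predictions exactly -> all terms zero
  exact <- labeled_dataset(list(list(coords = x, fidelity = "f",
                                     energies = p$energies,
                                     gradients = p$gradients, weight = 1)))
  l0 <- surrogate_loss(exact, s, loss_weights(1, 1, 1))
  expect_equal(l0$total, 0, tolerance = 1e-24)
  expect_equal(l0$energy, 0, tolerance = 1e-24)
  expect_equal(l0$gap, 0, tolerance = 1e-24)
  expect_equal(l0$force, 0, tolerance = 1e-24)

  ## single energy error e on one state with only the energy weight on
  e_err <- 3e-3
  shifted <- labeled_dataset(list(list(coords = x, fidelity = "f",
                                       energies = p$energies + c(e_err, 0),
                                       gradients = NULL, weight = 1)))
  l1 <- surrogate_loss(shifted, s, loss_weights(1, 0, 0))
  expect_equal(l1$total, e_err^2, tolerance = 1e-12)
  ## the same record with the gap weight on picks up the gap residual too
  l2 <- surrogate_loss(shifted, s, loss_weights(0, 1, 0))
  expect_equal(l2$total, e_err^2, tolerance = 1e-12)

  ## the default weights are 1, 1 and 0.1 for energies, gaps, gradients
  w <- loss_weights()
  expect_equal(c(w$w_energy, w$w_gap, w$w_force), c(1, 1, 0.1))

  ## full-batch loss is invariant to batch ordering
  m <- model_linear_crossing()
  ds <- make_fixture_dataset(m, 30, -2, 2, seed = 5, fidelity = "f")
  l_fwd <- surrogate_loss(ds, s, loss_weights())
  l_rev <- surrogate_loss(labeled_dataset(rev(unclass(ds))), s, loss_weights())
  expect_equal(l_fwd$total, l_rev$total, tolerance = 1e-12)
})

test_that("parameter gradients of the loss match finite differences", {
  lvc <- model_lvc3()
  ds <- merge_datasets(
    make_fixture_dataset(lvc, 8, c(-1, -1), c(2, 1), seed = 1, fidelity = "hi"),
    make_fixture_dataset(lvc, 6, c(-1, -1), c(2, 1), seed = 2, fidelity = "lo",
                         include_gradients = FALSE))
  s <- build_surrogate(2, 3, c("hi", "lo"), hidden = c(7, 5), seed = 3)
  lab <- gfnamd:::surrogate_labels(s, ds)
  U <- gfnamd:::surrogate_inputs(s, lab$coords, lab$fids)
  w <- loss_weights(1, 0.7, 0.4)
  res <- gfnamd:::nn_loss(s, U, lab$E, lab$gmask, lab$Garr, w, with_grad = TRUE)
  g <- gfnamd:::nn_pack(res$grad)
  th0 <- gfnamd:::nn_pack(s$par)
  idx <- round(seq(1, length(th0), length.out = 15))
  for (i in idx) {
    fd <- 0
    for (sgn in c(1, -1)) {
      th <- th0; th[i] <- th[i] + sgn * 1e-6
      s$par <- gfnamd:::nn_unpack(th, s$shapes)
      fd <- fd + sgn * gfnamd:::nn_loss(s, U, lab$E, lab$gmask, lab$Garr, w)$total / 2e-6
    }
    expect_lt(abs(fd - g[i]) / max(abs(g[i]), 1e-6), 1e-4)
  }
})

test_that("training converges on a constant-energy dataset", {
  recs <- lapply(1:40, function(i) list(coords = i / 40, fidelity = "f",
                                        energies = c(-0.5, -0.3), weight = 1))
  s <- build_surrogate(1, 2, "f", hidden = c(8), seed = 1)
  s <- train_surrogate(s, labeled_dataset(recs),
                       schedule = training_schedule(initial_lr = 0.03,
                                                    batch_size = 8,
                                                    max_epochs = 600, seed = 1))
  r <- residuals(s, labeled_dataset(recs))
  expect_lt(max(abs(r)), 1e-3)
})

test_that("energy-only training on 500 linear-crossing points reaches sub-millihartree accuracy", {
  m <- model_linear_crossing()
  ds <- make_fixture_dataset(m, 500, -4, 4, seed = 11, fidelity = "ref",
                             include_gradients = FALSE)
  held <- make_fixture_dataset(m, 150, -3.8, 3.8, seed = 99, fidelity = "ref",
                               include_gradients = FALSE)
  s <- build_surrogate(1, 2, "ref", hidden = c(32, 32), seed = 5)
  s <- train_surrogate(s, ds, schedule = training_schedule(batch_size = 32,
                                                           seed = 2,
                                                           max_epochs = 2000))
  expect_lt(mean(abs(residuals(s, held))), 1e-3)
  ## the energy-only model still returns forces, close to the reference
  p <- predict(s, 1.1, with_forces = TRUE)
  ref <- evaluate_adiabatic(m, 1.1)
  expect_lt(max(abs(p$gradients - ref$gradients)), 5e-3)
})

test_that("training errors are informative", {
  recs <- labeled_dataset(lapply(1:10, function(i)
    list(coords = i, fidelity = "a", energies = c(0, 1), weight = 1)))
  s <- build_surrogate(1, 2, c("a", "b"), hidden = c(4), seed = 1)
  expect_error(train_surrogate(s, recs), "fidelity")
  s2 <- build_surrogate(1, 2, "a", hidden = c(4), seed = 1)
  expect_error(train_surrogate(s2, recs, validation_fraction = 0.99),
               "validation")
  expect_error(
    labeled_dataset(list(list(coords = 1, fidelity = "a",
                              energies = c(0, 1),
                              gradients = matrix(0, 3, 2), weight = 1))),
    "n_states x n_coords")
})

test_that("ensembles average members and quantify spread", {
  s <- build_surrogate(1, 2, "f", hidden = c(5), seed = 1)
  ## identical members -> zero uncertainty
  ens <- suppressWarnings(surrogate_ensemble(list(s, s, s)))
  p <- ensemble_predict(ens, 0.2, "f")
  expect_equal(p$uncertainty, c(0, 0), tolerance = 1e-15)
  ## single member -> defined as zero with a warning
  expect_warning(e1 <- surrogate_ensemble(list(s)), "single-member")
  expect_equal(ensemble_predict(e1, 0.2, "f")$uncertainty, c(0, 0))

  ## members with known constant offsets: mean and sd computed by hand
  offs <- c(-0.004, -0.001, 0.001, 0.004)
  members <- lapply(offs, function(o) {
    si <- s
    si$e_center <- si$e_center + o
    si
  })
  ens4 <- surrogate_ensemble(members)
  p0 <- predict(s, 0.2, "f")
  p4 <- ensemble_predict(ens4, 0.2, "f")
  expect_equal(p4$energies, p0$energies + mean(offs), tolerance = 1e-12)
  expect_equal(p4$uncertainty, rep(sd(p0$energies[1] + offs), 2),
               tolerance = 1e-12)

  ## ensemble mean is permutation-invariant in the members
  perm <- surrogate_ensemble(members[c(3, 1, 4, 2)])
  expect_equal(ensemble_predict(perm, 0.2, "f")$energies, p4$energies,
               tolerance = 1e-15)
})

test_that("the fast propagation evaluator agrees with predict()", {
  lvc <- model_lvc3()
  ds <- make_fixture_dataset(lvc, 60, c(-1, -1), c(2, 1), seed = 6,
                             fidelity = "f")
  s <- build_surrogate(2, 3, "f", hidden = c(12, 12), seed = 2)
  s <- train_surrogate(s, ds, schedule = quick_schedule(max_epochs = 60))
  ev <- gfnamd:::make_evaluator(s, "f")
  for (x in list(c(0.5, 0.2), c(-0.4, 0.9))) {
    a <- ev(x)
    b <- predict(s, x, "f", with_forces = TRUE)
    expect_equal(a$energies, b$energies, tolerance = 1e-14)
    expect_equal(a$gradients, b$gradients, tolerance = 1e-12)
  }
})
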