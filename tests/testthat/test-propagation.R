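## uncoupled two-state model whose lower surface is a harmonic well;
## the upper state is far away, so dynamics is effectively single-state
harmonic_model <- function(k = 0.2, mass = 2000, offset = 10) {
  diabatic_model(
    "harmonic", 1L, 2L, mass, list(k = k, offset = offset),
    vfun = function(x, p) diag(c(0.5 * p$k * x^2, p$offset + 0.5 * p$k * x^2)),
    dvfun = function(x, p) array(c(p$k * x, 0, 0, p$k * x), c(2, 2, 1)))
}

test_that("velocity Verlet is symplectic and reproduces the harmonic period", {
  m <- harmonic_model()
  omega <- sqrt(0.2 / 2000)
  period_fs <- au_to_fs(2 * pi / omega)
  st <- propagation_settings(dt_fs = period_fs / 1000, t_max_fs = period_fs,
                             seed = 1)
  tr <- propagate(m, list(coords = 0.1, velocities = 0, state = 1), st)
  te <- total_energy(tr)
  expect_lt(max(abs(te - te[1])), 1e-8)
  expect_identical(tr$termination, "completed")
  expect_equal(nrow(tr$hops), 0L)     # no competing surface in reach

  ## period from zero crossings of x(t)
  x <- tr$coords[, 1]
  crossings <- which(diff(sign(x)) != 0)
  measured <- 2 * diff(tr$times_fs[crossings[1:2]])
  expect_equal(measured, period_fs, tolerance = 1e-3)

  ## zero force, zero velocity: a fixed point
  st0 <- list(t = 0, coords = 0, velocities = 0, active_state = 1L)
  out <- velocity_verlet_step(st0, m, fs_to_au(0.1), masses = 2000)
  expect_equal(out$coords, 0)
  expect_equal(out$velocities, 0)
})

test_that("gap-minimum detection uses strict inequalities", {
  w <- function(z) gap_window(z, c(0, 1, 2))
  expect_true(detect_gap_minimum(w(c(0.5, 0.3, 0.4))))
  expect_false(detect_gap_minimum(w(c(0.5, 0.4, 0.3))))
  expect_false(detect_gap_minimum(w(c(0.3, 0.3, 0.3))))   # plateau: no hop
  expect_false(detect_gap_minimum(w(c(0.3, 0.3, 0.4))))
  expect_error(gap_window(c(1, 2, 3), c(0, 1, 2.5)), "equally spaced")
})

test_that("the LZBL probability follows the gap formula and its limits", {
  dt <- 2
  ## exact degeneracy at the minimum: certain hop
  expect_equal(lzbl_probability(gap_window(c(1e-3, 0, 1e-3), c(0, dt, 2 * dt))),
               1)
  ## large gap, small curvature: vanishing probability
  expect_lt(lzbl_probability(gap_window(c(0.5 + 1e-7, 0.5, 0.5 + 1e-7),
                                        c(0, dt, 2 * dt))), 1e-10)
  ## direct arithmetic: P = exp(-(pi/2) sqrt(Z^3 / Zdd))
  z <- c(0.013, 0.010, 0.012)
  zdd <- (z[1] - 2 * z[2] + z[3]) / dt^2
  expect_equal(lzbl_probability(gap_window(z, c(0, dt, 2 * dt))),
               exp(-(pi / 2) * sqrt(z[2]^3 / zdd)), tolerance = 1e-14)
  expect_error(lzbl_probability(gap_window(c(0.1, 0.2, 0.3), c(0, dt, 2 * dt))),
               "contract")
})

test_that("velocity rescaling conserves total energy exactly", {
  v <- c(0.01, -0.02, 0.005); m <- c(1800, 2000, 2200)
  expect_identical(rescale_velocities(v, m, 0), v)
  ## KE = 0.01, delta_e = 0.01 -> speed scales by sqrt(2)
  v1 <- c(sqrt(2 * 0.01 / 2000)); m1 <- 2000
  expect_equal(rescale_velocities(v1, m1, 0.01), v1 * sqrt(2), tolerance = 1e-14)
  set.seed(5)
  for (i in 1:50) {
    v <- stats::rnorm(3, 0, 0.01); m <- stats::runif(3, 1500, 2500)
    ke <- 0.5 * sum(m * v^2)
    de <- stats::runif(1, -0.9, 2) * ke
    v2 <- rescale_velocities(v, m, de)
    expect_lt(abs(0.5 * sum(m * v2^2) - (ke + de)), 1e-12)
  }
  expect_error(rescale_velocities(v1, m1, -0.02), "frustrated")
})

test_that("hop attempts respect probability and the kinetic-energy veto", {
  st <- list(t = 0, coords = 0, velocities = 0.003, active_state = 1L,
             energies = c(-0.1, -0.08))
  ## p = 0: never hops
  set.seed(1)
  for (i in 1:20) {
    r <- attempt_hop(st, 2L, 0, masses = 2000)
    expect_false(r$event$accepted)
    expect_false(r$event$frustrated)
  }
  ## p = 1 downward: always hops, exact energy bookkeeping
  std <- st; std$active_state <- 2L
  r <- attempt_hop(std, 1L, 1, masses = 2000)
  expect_true(r$event$accepted)
  e_pre <- 0.5 * 2000 * std$velocities^2 + std$energies[2]
  e_post <- 0.5 * 2000 * r$state$velocities^2 + std$energies[1]
  expect_lt(abs(e_post - e_pre), 1e-12)
  ## p = 1 upward with KE below the gap: frustrated, state unchanged
  ke <- 0.5 * 2000 * st$velocities^2
  expect_lt(ke, diff(st$energies))
  r2 <- attempt_hop(st, 2L, 1, masses = 2000)
  expect_false(r2$event$accepted)
  expect_true(r2$event$frustrated)
  expect_identical(r2$state$active_state, 1L)
  ## the reduced reservoir makes an otherwise allowed upward hop frustrated
  st3 <- st; st3$velocities <- sqrt(2 * 0.03 / 2000)   # KE = 0.03 > gap = 0.02
  r3 <- attempt_hop(st3, 2L, 1, masses = 2000)
  expect_true(r3$event$accepted)
  r4 <- attempt_hop(st3, 2L, 1, masses = 2000, reservoir_reduced = TRUE,
                    n_dof = 2L)                        # 0.015 < gap
  expect_true(r4$event$frustrated)
})

test_that("propagation runs the requested number of steps and records every frame", {
  m <- model_linear_crossing()
  st <- propagation_settings(dt_fs = 0.1, t_max_fs = 60, seed = 1)
  tr <- propagate(m, list(coords = -6, velocities = 0.002, state = 1), st)
  expect_length(tr$times_fs, 601)       # 600 steps + initial frame
  expect_equal(tr$times_fs[601], 60)
  expect_true(all(diff(tr$times_fs) > 0))
  ## hop times coincide with frame times
  if (nrow(tr$hops) > 0)
    expect_true(all(tr$hops$time_fs %in% tr$times_fs))
})

test_that("ensemble transition fraction matches the Landau-Zener oracle and is stable in dt", {
  m <- model_linear_crossing()
  x0 <- -2; v0 <- 0.011
  E1 <- function(x) -sqrt((0.01 * x)^2 + 0.005^2)
  vc <- sqrt(2 * (0.5 * 2000 * v0^2 + E1(x0) - E1(0)) / 2000)
  p_ref <- landau_zener_reference(0.005, 0.02, vc)
  ini <- list(coords = x0, velocities = v0, state = 1)
  frac <- sapply(c(0.1, 0.05), function(dt) {
    st <- propagation_settings(dt_fs = dt, t_max_fs = 12, seed = 1)
    ens <- run_ensemble(m, replicate(500, ini, simplify = FALSE), st,
                        base_seed = 40)
    mean(vapply(ens, function(tr) tr$active[length(tr$active)] == 2L, TRUE))
  })
  ci <- binomial_ci(p_ref, 500)
  expect_lt(abs(frac[1] - p_ref), ci)
  ## halving dt moves the fraction by less than the binomial CI
  expect_lt(abs(frac[2] - frac[1]), ci)
})

test_that("ensembles are reproducible, tallied, and fail loudly only on empty input", {
  lvc <- model_lvc3()
  inis <- lapply(wigner_sample(lvc3_normal_modes(lvc), 12, seed = 8),
                 function(s) list(coords = s$coords,
                                  velocities = s$velocities, state = 3))
  st <- propagation_settings(dt_fs = 0.1, t_max_fs = 10, seed = 1)
  e1 <- run_ensemble(lvc, inis, st, base_seed = 5)
  e2 <- run_ensemble(lvc, inis, st, base_seed = 5)
  expect_identical(e1, e2)
  tal <- termination_tally(e1)
  expect_equal(sum(tal$n), 12)
  expect_equal(sum(tal$percent), 100)
  ## analytic potentials report zero uncertainty: no uncertainty stops
  expect_false(any(vapply(e1, function(tr)
    tr$termination == "uncertainty_exceeded", TRUE)))
  expect_error(run_ensemble(lvc, list(), st, 1), "no initial conditions")
})

test_that("distortion and uncertainty predicates terminate trajectories gracefully", {
  m <- model_linear_crossing()
  st <- propagation_settings(dt_fs = 0.1, t_max_fs = 30, seed = 1,
                             distortion_check = function(x, x0)
                               abs(x - x0) > 1)
  tr <- propagate(m, list(coords = -3, velocities = 0.01, state = 1), st)
  expect_identical(tr$termination, "distorted")
  expect_lt(tr$times_fs[length(tr$times_fs)], 30)
})
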