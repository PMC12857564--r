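test_that("populations partition the ensemble and track hop times", {
  trs <- list(hopping_trajectory(10), hopping_trajectory(25),
              hopping_trajectory(Inf))
  pop <- populations(trs, grid_fs = seq(0, 60, by = 1))
  ## everything starts in S1
  expect_equal(pop$populations[1, ], c(0, 1))
  ## single-trajectory step function behaviour at the hop time
  p1 <- populations(list(hopping_trajectory(10)), grid_fs = c(9, 10, 11))
  expect_equal(p1$populations[, 1], c(0, 1, 1))
  ## populations always sum to one
  expect_true(all(abs(rowSums(pop$populations) - 1) < 1e-12))
  ## two-state identity P(S1) = 1 - P(S0)
  expect_equal(pop$populations[, 2], 1 - pop$populations[, 1])
  expect_error(populations(list()), "no trajectories")
})

test_that("binomial half-widths follow the normal-approximation formula", {
  ## z * sqrt(p(1-p)/n) with z = 1.959964 at 95%
  expect_equal(binomial_ci(0.5, 1000), 1.959964 * sqrt(0.25 / 1000),
               tolerance = 1e-6)
  expect_identical(binomial_ci(0, 50), 0)
  expect_identical(binomial_ci(1, 50), 0)
  ## 1/sqrt(n) scaling
  expect_equal(binomial_ci(0.3, 100) / binomial_ci(0.3, 400), 2,
               tolerance = 1e-12)
  expect_error(binomial_ci(0.5, 0), ">= 1")
  expect_error(binomial_ci(1.2, 10), "\\[0, 1\\]")
})

test_that("bootstrap errors agree with the binomial formula on a Bernoulli ensemble", {
  set.seed(3)
  n <- 600
  hop_times <- ifelse(stats::runif(n) < 0.4, 5, Inf)   # P(S0) = 0.4 for t >= 5
  trs <- lapply(hop_times, hopping_trajectory, times_fs = seq(0, 20, by = 5))
  se <- bootstrap_populations(trs, grid_fs = 10, n_boot = 1000, seed = 1)
  expect_equal(se[1, 1], binomial_ci(0.4, n) / 1.959964, tolerance = 0.1)
  ## identical trajectories: no variability
  same <- lapply(rep(5, 30), hopping_trajectory, times_fs = seq(0, 20, by = 5))
  expect_equal(max(bootstrap_populations(same, grid_fs = 10, n_boot = 50,
                                         seed = 1)), 0)
  ## determinism and the reduced-fraction resampling mode
  s1 <- bootstrap_populations(trs, grid_fs = 10, n_boot = 200, seed = 7,
                              fraction = 0.55)
  s2 <- bootstrap_populations(trs, grid_fs = 10, n_boot = 200, seed = 7,
                              fraction = 0.55)
  expect_identical(s1, s2)
  ## resampling 55% of the ensemble widens the spread by ~1/sqrt(0.55)
  s_full <- bootstrap_populations(trs, grid_fs = 10, n_boot = 1000, seed = 7)
  s_red <- bootstrap_populations(trs, grid_fs = 10, n_boot = 1000, seed = 7,
                                 fraction = 0.55)
  expect_equal(s_red[1, 1] / s_full[1, 1], 1 / sqrt(0.55), tolerance = 0.15)
  ## caller-supplied reducer path
  se_phi <- bootstrap_populations(trs, n_boot = 300, seed = 2,
                                  reducer = function(tt)
                                    mean(vapply(tt, function(tr)
                                      tr$active[length(tr$active)] == 1L, TRUE)))
  expect_equal(se_phi, binomial_ci(0.4, n) / 1.959964, tolerance = 0.15)
})

test_that("decay fits recover exact and binomial-noise parameters", {
  t <- seq(0, 400, by = 0.5)
  p_exact <- ifelse(t >= 20, 1 - exp(-(t - 20) / 100), 0)
  cv <- list(times_fs = t, populations = matrix(p_exact, ncol = 1))
  f <- fit_decay(cv, 1, "delayed")
  expect_equal(f$tau, 100, tolerance = 1e-6)
  expect_equal(f$t0, 20, tolerance = 1e-6)
  expect_equal(predict(f, c(10, 20, 120)), c(0, 0, 1 - exp(-1)),
               tolerance = 1e-6)

  ## plain form on a curve without lag gives the same tau as the delayed form
  p0 <- 1 - exp(-t / 80)
  cv0 <- list(times_fs = t, populations = matrix(p0, ncol = 1))
  expect_equal(fit_decay(cv0, 1, "plain")$tau,
               fit_decay(cv0, 1, "delayed")$tau, tolerance = 1e-4)

  ## binomial noise at n = 1000 trajectories: tau within 2 SE
  set.seed(9)
  pn <- stats::rbinom(length(t), 1000, p_exact) / 1000
  fn <- fit_decay(list(times_fs = t, populations = matrix(pn, ncol = 1)),
                  1, "delayed")
  expect_lt(abs(fn$tau - 100), 2 * max(fn$tau_se, 1))
  expect_warning(
    fit_decay(list(times_fs = t[t < 30],
                   populations = matrix(p_exact[t < 30], ncol = 1)),
              1, "delayed"), "half")
})

test_that("product classifiers apply strict thresholds as printed", {
  rule_open <- classifier_rule("distance", c(1, 2), 1.8, label_above = "open",
                               label_below = "closed", unit = "angstrom")
  geom <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  expect_identical(classify_product(geom(1.9), rule_open), "open")
  expect_identical(classify_product(geom(1.7), rule_open), "closed")
  expect_identical(classify_product(geom(1.8), rule_open), "closed")  # tie

  rule_cis <- classifier_rule("dihedral", 1:4, 60, label_above = "trans",
                              label_below = "cis", unit = "angstrom")
  dihedral_geom <- function(phi) {
    phi <- phi * pi / 180
    rbind(c(1, 0, -1), c(0, 0, -1), c(0, 0, 0),
          c(cos(phi), sin(phi), 0))
  }
  expect_identical(classify_product(dihedral_geom(55), rule_cis), "cis")
  expect_identical(classify_product(dihedral_geom(170), rule_cis), "trans")
  ## strict "<": just below the threshold is cis, at/above is trans
  expect_identical(classify_product(dihedral_geom(59.99), rule_cis), "cis")
  expect_identical(classify_product(dihedral_geom(60.01), rule_cis), "trans")
  expect_error(classify_product(geom(1), classifier_rule("distance", c(1, 5), 1)),
               "out of range")
})

test_that("geometric measures follow the standard conventions", {
  ## planar trans chain: dihedral 180; planar cis: 0
  chain <- function(phi) {
    phi <- phi * pi / 180
    rbind(c(1, 0, -1), c(0, 0, -1), c(0, 0, 0), c(cos(phi), sin(phi), 0))
  }
  expect_equal(measure_geometry(chain(180), "dihedral", 1:4,
                                unit = "angstrom"), 180)
  expect_equal(measure_geometry(chain(0), "dihedral", 1:4, unit = "angstrom"),
               0)
  ## right angle
  tri <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_equal(measure_geometry(tri, "angle", 1:3, unit = "angstrom"), 90)
  ## distances convert bohr -> angstrom
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(measure_geometry(two, "distance", 1:2, unit = "bohr"),
               0.529177210903)
  ## mirroring the geometry negates the dihedral
  g <- chain(72)
  gm <- g; gm[, 3] <- -gm[, 3]
  expect_equal(measure_geometry(gm, "dihedral", 1:4, unit = "angstrom"),
               -measure_geometry(g, "dihedral", 1:4, unit = "angstrom"))
  expect_error(measure_geometry(rbind(c(0,0,0), c(1,0,0), c(2,0,0), c(3,0,0)),
                                "dihedral", 1:4), "collinear")
  expect_error(measure_geometry(two, "angle", 1:2), "3 atom")
})

test_that("quantum yields count reactive trajectories with a binomial interval", {
  rule <- classifier_rule("coordinate", 1, 2.0, label_above = "open",
                          label_below = "closed")
  trs <- c(lapply(rep(3, 5), stub_trajectory),   # open
           lapply(rep(1, 5), stub_trajectory))   # closed
  y <- quantum_yield(trs, rule)
  expect_equal(y$phi, 0.5)
  expect_equal(y$n_reactive, 5L)
  ## none reactive: zero yield and zero width
  y0 <- quantum_yield(lapply(rep(1, 10), stub_trajectory), rule)
  expect_equal(y0$phi, 0)
  expect_equal(y0$ci_half_width, 0)
  ## distorted/uncertain trajectories are excluded from classification
  mixed <- c(trs, list(stub_trajectory(5, termination = "distorted"),
                       stub_trajectory(5, termination = "uncertainty_exceeded")))
  expect_equal(quantum_yield(mixed, rule)$n_traj, 10L)
  ## a Bernoulli ensemble with true rate 0.53 is covered by the 95% CI
  set.seed(4)
  bern <- lapply(ifelse(stats::runif(1000) < 0.53, 3, 1), stub_trajectory)
  yb <- quantum_yield(bern, rule)
  expect_lt(abs(yb$phi - 0.53), binomial_ci(0.53, 1000))
  expect_error(quantum_yield(list(), rule), "no trajectories")
})

test_that("hop tables aggregate per-product statistics correctly", {
  ## five accepted hops with known times across three trajectories
  t1 <- hopping_trajectory(10); t1$coords[, 1] <- 3       # ends open
  t2 <- hopping_trajectory(20); t2$coords[, 1] <- 3       # ends open
  t3 <- hopping_trajectory(30); t3$coords[, 1] <- 1       # ends closed
  rule <- classifier_rule("coordinate", 1, 2.0, label_above = "open",
                          label_below = "closed")
  tab <- hop_statistics(list(t1, t2, t3), pair = c(2, 1),
                        measures = list(x = function(g) g[1]), rule = rule)
  expect_equal(nrow(tab), 3L)
  means <- attr(tab, "product_means")
  expect_equal(unname(means["open"]), 15)
  expect_equal(unname(means["closed"]), 30)
  ## empty request gives an empty table, not an error
  empty <- hop_statistics(list(t1), pair = c(2, 3))
  expect_equal(nrow(empty), 0L)
})

test_that("branching ratios are counted inside the CI window", {
  tab <- data.frame(
    dihedral = c(rep(95, 3), rep(100, 9), rep(170, 2)),
    product = c(rep("cis", 3), rep("trans", 9), rep("trans", 2)))
  class(tab) <- c("hop_table", "data.frame")
  b <- branching_ratio(tab, ci_dihedral = 95, window_halfwidth = 20,
                       first_label = "cis")
  expect_equal(b$gamma, 3)                  # cis : trans = 1 : 3
  expect_equal(b$n_inside, 12L)
  expect_equal(b$n_outside, 2L)
  expect_equal(b$fraction_outside, 2 / 14)
  ## equal split: 1 : 1
  tab2 <- tab[c(1:3, 4:6), ]
  expect_equal(branching_ratio(tab2, 95, 20, first_label = "cis")$gamma, 1)
  expect_warning(branching_ratio(tab, 0, 5), "undefined")
})

test_that("interpolated paths are linear with included endpoints", {
  a <- c(0, 0, 1); b <- c(2, 4, -1)
  p2 <- liic_path(a, b, 2)
  expect_identical(p2[[1]], a)
  expect_identical(p2[[2]], b)
  p3 <- liic_path(a, b, 3)
  expect_equal(p3[[2]], (a + b) / 2)
  ## energies along the path on a quadratic surface form a parabola
  quad <- function(x) sum(x^2)
  e <- vapply(liic_path(a, b, 9), quad, 0)
  s <- seq(0, 1, length.out = 9)
  fit <- lm(e ~ s + I(s^2))
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_error(liic_path(a, b[1:2], 3), "mismatch")
  expect_error(liic_path(a, b, 1), "endpoints")
})
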