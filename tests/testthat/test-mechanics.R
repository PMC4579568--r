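test_that("torsional_stiffness implements the equipartition relation", {
  expect_equal(torsional_stiffness(13.7, 4.045), 70.8, tolerance = 1e-3)
  expect_equal(torsional_stiffness(11.5, 4.045), 100.4, tolerance = 1e-3)
  expect_equal(torsional_stiffness(180 / pi, 4.045), 4.045)  # sigma = 1 rad
  expect_error(torsional_stiffness(0), "domain error")
})

test_that("cantilever_stiffness converts torsional to axial stiffness", {
  expect_equal(cantilever_stiffness(72, 12.3, 41.9), 1.067, tolerance = 1e-3)
  expect_equal(cantilever_stiffness(101, 12.3, 41.5), 1.52, tolerance = 5e-3)
  expect_equal(cantilever_stiffness(88, 12.3, 90), 88 / 12.3^2)
  expect_error(cantilever_stiffness(72, 12.3, 0), "domain error")
})

test_that("cantilever and torsional stiffness close algebraically", {
  set.seed(31)
  kappa <- runif(20, 30, 150)
  lever <- runif(20, 5, 20)
  phi <- runif(20, 10, 90)
  k <- cantilever_stiffness(kappa, lever, phi)
  expect_equal(k * (lever * sin(phi * pi / 180))^2, kappa)
})

test_that("ols_fit matches the closed-form normal equations", {
  x <- seq(0, 25, length.out = 50)
  fit <- ols_fit(x, 40 + 0.222 * x)
  expect_equal(fit$slope, 0.222, tolerance = 1e-10)
  expect_equal(fit$intercept, 40.0, tolerance = 1e-10)

  set.seed(32)
  for (i in 1:20) {
    x <- runif(30, 0, 25)
    y <- 40 + rnorm(30, sd = 5)
    fit <- ols_fit(x, y)
    want <- ols_oracle(x, y)
    expect_equal(fit$slope, want$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-9)
  }
  expect_error(ols_fit(1:2, 1:2), "fit error")
  expect_error(ols_fit(rep(1, 5), 1:5), "fit error")
})

test_that("running_stats equals naive per-window recomputation", {
  set.seed(33)
  x <- sort(runif(359, 0, 25))
  y <- 40 + 0.2 * x + rnorm(359, sd = 5)
  rs <- running_stats(x, y, 100)
  expect_equal(nrow(rs), 260)  # n - window + 1
  expect_equal(rs, running_stats_oracle(x, y, 100), tolerance = 1e-12)
  one <- running_stats(x[1:100], y[1:100], 100)
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_y, mean(y[1:100]))
  expect_error(running_stats(x[1:50], y[1:50], 100), "size error")
})

test_that("pairwise_difference_slope subtracts trailing from leading", {
  f <- function(m) structure(list(slope = m, intercept = 0, n = 10),
                             class = "regression_fit")
  expect_equal(pairwise_difference_slope(f(-0.200), f(0.222)), -0.422)
  expect_equal(pairwise_difference_slope(f(0.1), f(0.1)), 0)
  expect_equal(pairwise_difference_slope(f(-0.3), f(0.3)), -0.6)
})

test_that("tension_per_nm reproduces the published torque-balance estimates", {
  expect_equal(tension_per_nm(71, 0.222, 12.3, 42.7), 0.033, tolerance = 2e-3)
  expect_equal(tension_per_nm(72, 0.200, 12.3, 41.9), 0.0306, tolerance = 1e-3)
  expect_equal(tension_per_nm(0, 0.2, 12.3, 42), 0)
  expect_error(tension_per_nm(71, 0.2, 12.3, 0), "singular")
})

test_that("tension_at scales linearly with separation", {
  expect_equal(tension_at(16.6, 0.032), 0.531, tolerance = 1e-3)
  expect_equal(tension_at(24.9, 0.032), 0.797, tolerance = 1e-3)
  expect_equal(tension_at(0, 0.05), 0)
})

test_that("ring_sep_from_regressions reproduces the published linearization", {
  ft <- structure(list(slope = 0.222, intercept = 40.0, n = 359),
                  class = "regression_fit")
  fl <- structure(list(slope = -0.200, intercept = 44.1, n = 359),
                  class = "regression_fit")
  got <- ring_sep_from_regressions(c(0.9, 8.3, 16.6, 24.9), ft, fl, 18.8)
  expect_equal(got, c(-0.1, 6.6, 14.2, 21.7), tolerance = 0.05)
  expect_equal(got[3], 14.16, tolerance = 1e-2)
  # degenerate fits: zero slopes, equal intercepts -> identity
  f0 <- structure(list(slope = 0, intercept = 42, n = 10),
                  class = "regression_fit")
  expect_equal(ring_sep_from_regressions(c(0, 5, 10), f0, f0), c(0, 5, 10))
  # geometric mode is self-consistent with the forward geometry
  geo <- ring_sep_from_regressions(16.6, ft, fl, 18.8, mode = "geometric")
  th_t <- (40.0 + 0.222 * 16.6) * pi / 180
  th_l <- (44.1 - 0.200 * 16.6) * pi / 180
  expect_equal(geo, 16.6 - 18.8 * cos(th_l) + 18.8 * cos(th_t))
  expect_error(ring_sep_from_regressions(1, ft, fl, 18.8, mode = "bogus"))
})

test_that("tether_stiffness divides tension increment by ring-sep increment", {
  expect_equal(tether_stiffness(0.53 - 0.26, 14.2 - 6.6), 0.0355,
               tolerance = 2e-3)
  expect_equal(tether_stiffness(0, 5), 0)
  expect_error(tether_stiffness(0.1, 0), "singular")
  # consistency: per-nm tension / d(ring_sep)/dx gives the same stiffness
  ft <- structure(list(slope = 0.222, intercept = 40.0, n = 359),
                  class = "regression_fit")
  fl <- structure(list(slope = -0.200, intercept = 44.1, n = 359),
                  class = "regression_fit")
  drs_dx <- diff(ring_sep_from_regressions(c(8.3, 16.6), ft, fl, 18.8)) / 8.3
  per_nm_mean <- mean(c(tension_per_nm(71, 0.222, 12.3, 42.7),
                        tension_per_nm(72, 0.200, 12.3, 41.9)))
  expect_equal(per_nm_mean / drs_dx, 0.0355, tolerance = 0.02)
})

test_that("equilibrium_constant is the superposed/offset frequency ratio", {
  expect_equal(equilibrium_constant(318, 31), 10.26, tolerance = 1e-3)
  expect_equal(equilibrium_constant(50, 50), 1)
  expect_equal(equilibrium_constant(0, 10), 0)
  expect_error(equilibrium_constant(10, 0), "singular")
})

test_that("equipartition recovers generator stiffness without tether", {
  geom <- motor_geometry()
  for (kappa_true in c(50, 101)) {
    mech <- mechanical_params(kappa_leading = kappa_true,
                              kappa_trailing = kappa_true,
                              tether_stiffness = 0)
    o <- sample_offset_dimers(mech, geom, 8.3, 2e4, 500 + kappa_true)
    kap <- torsional_stiffness(sd(o$theta_trailing), mech$thermal_energy)
    expect_equal(kap, kappa_true, tolerance = 0.05)
  }
})

test_that("mechanics_report runs the full chain on synthetic dimers", {
  mech <- mechanical_params()
  geom <- motor_geometry()
  seps <- c(0.9, 8.3, 16.6, 24.9)
  sets <- lapply(seq_along(seps), function(i) {
    o <- sample_offset_dimers(mech, geom, seps[i], 2000, 600 + i)
    data.frame(theta_trail_deg = o$theta_trailing,
               theta_lead_deg = o$theta_leading,
               stalkhead_separation_nm = seps[i],
               ring_separation_nm = NA_real_)
  })
  dimers <- do.call(rbind, sets)
  sup <- sample_superposed_dimers(mech, geom, 2000, 611)$theta
  rep <- mechanics_report(dimers, sup, geom, mode = "geometric")
  # regression signs as observed: trailing steepens, leading shallows
  expect_gt(rep$fit_trailing$slope, 0)
  expect_lt(rep$fit_leading$slope, 0)
  expect_lt(rep$pairwise_slope, 0)
  expect_equal(rep$trailing$kappa, 71, tolerance = 0.15)
  expect_equal(rep$superposed$kappa, 101, tolerance = 0.10)
  expect_equal(rep$tether_stiffness, 0.035, tolerance = 0.25)
  expect_equal(nrow(rep$running_trailing), nrow(dimers) - 100 + 1)
  expect_named(rep$tensions_at, c("0.9", "8.3", "16.6", "24.9"))
})
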