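test_that("superposed sampler satisfies equipartition and matches quadrature", {
  mech <- mechanical_params(kappa_superposed = 100.4)
  geom <- motor_geometry()
  s <- sample_superposed_dimers(mech, geom, 5e4, 101)
  oracle <- quad_moments_1d(100.4, 42, mech$thermal_energy)
  # chains are thinned but not fully independent: allow 3 s.e. computed
  # with a conservative effective sample size of n/10
  se_mean <- oracle$sd_deg / sqrt(5e3)
  expect_lt(abs(mean(s$theta) - oracle$mean_deg), 3 * se_mean)
  expect_lt(abs(sd(s$theta) - oracle$sd_deg) / oracle$sd_deg, 0.03)
  # printed s.d. of the superposed class
  expect_equal(sd(s$theta), 11.5, tolerance = 0.03)
})

test_that("superposed sampler collapses onto the rest angle in the stiff limit", {
  mech <- mechanical_params(kappa_superposed = 1e6)
  s <- sample_superposed_dimers(mech, motor_geometry(), 5e3, 7)
  expect_equal(mean(s$theta), 42, tolerance = 0.01)
  expect_lt(sd(s$theta), 0.12)  # ~0.065 deg expected
})

test_that("offset sampler without tether is two independent equipartition springs", {
  mech <- mechanical_params(kappa_leading = 70.75, kappa_trailing = 70.75,
                            tether_stiffness = 0)
  o <- sample_offset_dimers(mech, motor_geometry(), 8.3, 5e4, 202)
  expect_equal(sd(o$theta_trailing), 13.7, tolerance = 0.03)
  expect_equal(sd(o$theta_leading), 13.7, tolerance = 0.03)
  expect_lt(abs(cor(o$theta_trailing, o$theta_leading)), 0.03)
})

test_that("offset sampler with tether matches 2-D grid quadrature", {
  mech <- mechanical_params()
  geom <- motor_geometry()
  o <- sample_offset_dimers(mech, geom, 16.6, 2e4, 303)
  oracle <- quad_moments_2d(mech, geom$lever_length, 16.6, n_grid = 400)
  se_t <- oracle$sd_trail_deg / sqrt(2e3)
  se_l <- oracle$sd_lead_deg / sqrt(2e3)
  expect_lt(abs(mean(o$theta_trailing) - oracle$mean_trail_deg), 3 * se_t)
  expect_lt(abs(mean(o$theta_leading) - oracle$mean_lead_deg), 3 * se_l)
  expect_equal(sd(o$theta_trailing), oracle$sd_trail_deg, tolerance = 0.04)
  expect_equal(sd(o$theta_leading), oracle$sd_lead_deg, tolerance = 0.04)
  # tether pulls angles apart: trailing steepens, leading shallows
  expect_gt(mean(o$theta_trailing), 42)
  expect_lt(mean(o$theta_leading), 42)
})

test_that("samplers reject inconsistent configurations and are reproducible", {
  geom <- motor_geometry()
  expect_error(
    sample_offset_dimers(mechanical_params(kappa_leading = 0), geom, 8.3, 10, 1),
    "configuration error")
  m <- mechanical_params()
  a <- sample_offset_dimers(m, geom, 8.3, 500, 99)
  b <- sample_offset_dimers(m, geom, 8.3, 500, 99)
  expect_identical(a, b)
  s1 <- sample_superposed_dimers(m, geom, 500, 99)
  s2 <- sample_superposed_dimers(m, geom, 500, 99)
  expect_identical(s1, s2)
})

test_that("to_particle_table writes the inverse geometry and round-trips", {
  geom <- motor_geometry()
  tab <- to_particle_table(42, 100, geom, noise_sd = 0)
  expect_equal(tab$ring_height_nm, 1.8 + 18.8 * sin(42 * pi / 180),
               tolerance = 1e-12)
  expect_equal(tab$ring_height_nm, 14.38, tolerance = 1e-3)
  # shallow angle: ring nearly ring_to_hinge behind the stalkhead
  tab0 <- to_particle_table(1e-6, 50, geom, noise_sd = 0)
  expect_equal(tab0$ring_height_nm, geom$hinge_height, tolerance = 1e-6)
  expect_equal(tab0$axial_x_nm, 50 - 18.8, tolerance = 1e-9)
  # round trip through the measurement module at zero noise
  theta <- runif(200, 5, 85)
  shx <- runif(200, 0, 2000)
  tab <- to_particle_table(theta, shx, geom, noise_sd = 0)
  th_rec <- stalk_angle(tab$ring_height_nm, geom)
  expect_lt(max(abs(as.numeric(th_rec) - theta)), 1e-9)
  expect_lt(max(abs(stalkhead_x(tab$axial_x_nm, th_rec, geom) - shx)), 1e-9)
  expect_error(to_particle_table(0, 10, geom), "theta")
})

test_that("place_on_mt is a reproducible Poisson placement", {
  p <- place_on_mt(2, 5000, 20, 55)
  expect_equal(nrow(p), 2 * 5000 / 100 * 20, tolerance = 0.15)
  expect_true(all(p$axial_x_nm >= 0 & p$axial_x_nm <= 5000))
  expect_identical(p, place_on_mt(2, 5000, 20, 55))
  empty <- place_on_mt(0, 5000, 5, 1)
  expect_equal(nrow(empty), 0)
})

test_that("simulate_runs follows the independent-heads geometric law", {
  r <- 0.902
  runs <- simulate_runs(r, 8.3, 1e5, 31)
  expect_equal(median(runs), 600, tolerance = 0.03)
  # per-cycle survival probability: fraction completing at least one step
  q <- 1 - (1 - r)^2
  p_hat <- mean(runs >= 8.3)
  expect_lt(abs(p_hat - q), 3 * sqrt(q * (1 - q) / 1e5))
  # r -> 0: immediate termination
  short <- simulate_runs(0.01, 8.3, 1e4, 5)
  expect_lt(median(short), 2 * 8.3)
  expect_error(simulate_runs(1, 8.3, 10, 1), "domain error")
  expect_error(simulate_runs(0, 8.3, 10, 1), "domain error")
})

test_that("generate_particles produces isolated, labelled, measurable dimers", {
  cfg <- gen_config(n_dimers = 300, seed = 17, measurement_noise_sd = 0)
  parts <- generate_particles(cfg)
  expect_true(all(c("particle_id", "mt_id", "axial_x_nm",
                    "ring_height_nm") %in% names(parts)))
  offs <- parts[parts$class_label == "offset", ]
  sups <- parts[parts$class_label == "superposed", ]
  # a handful of dimers may be dropped for unmeasurable sampled angles
  n_dimers <- nrow(offs) / 2 + nrow(sups)
  expect_lte(n_dimers, 300)
  expect_gte(n_dimers, 295)
  # zero noise: measured angles equal the generator's ground truth
  meas <- measure_particles(parts)
  expect_lt(max(abs(meas$theta_deg - meas$true_theta_deg)), 1e-9)
  # offset dimers recover their true stalkhead separation
  dt <- dimer_table(meas[meas$class_label == "offset", ])
  truth <- offs$true_separation_nm[seq(1, nrow(offs), 2)]
  expect_lt(max(abs(dt$stalkhead_separation_nm - truth)), 1e-9)
})

test_that("association equilibrium sets the superposed/offset ring ratio", {
  cfg <- gen_config(n_dimers = 3000, seed = 23, measurement_noise_sd = 0,
                    assoc_equilibrium = 10)
  parts <- generate_particles(cfg)
  n_sup <- sum(parts$class_label == "superposed")
  n_off_sup_stalkheads <- sum(parts$class_label == "offset" &
                                parts$true_separation_nm < 1) / 2
  K <- equilibrium_constant(n_sup, n_off_sup_stalkheads)
  expect_equal(K, 10, tolerance = 0.3)  # binomial counting error
})
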