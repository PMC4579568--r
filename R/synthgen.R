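#' @keywords internal
tether_attach_radius <- function(mech, geom) {
  if (is.null(mech$tether_attach)) geom$lever_length else mech$tether_attach
}

# Elastic energy (pN nm) of an offset dimer at angles (theta_t, theta_l) in
# radians. The tether elongation is the axial distance between the two
# stalk-base points: lattice_sep - a*cos(theta_l) + a*cos(theta_t), with a
# the tether attachment radius from the hinge.
offset_energy <- function(theta_t, theta_l, mech, a, lattice_sep) {
  th0 <- deg2rad(mech$rest_angle)
  elong <- lattice_sep - a * cos(theta_l) + a * cos(theta_t) -
    mech$tether_rest_separation
  0.5 * mech$kappa_trailing * (theta_t - th0)^2 +
    0.5 * mech$kappa_leading * (theta_l - th0)^2 +
    0.5 * mech$tether_stiffness * elong^2
}

# Vectorized Metropolis random walk over many independent chains.
# `state` is a matrix (chains x d); `energy(state)` returns a vector.
# Gaussian proposals of s.d. `prop_sd` (radians) on every coordinate.
metropolis_chains <- function(state, energy, kbt, n_iter, prop_sd) {
  e <- energy(state)
  m <- nrow(state)
  d <- ncol(state)
  for (it in seq_len(n_iter)) {
    prop <- state + matrix(stats::rnorm(m * d, sd = prop_sd), m, d)
    e_prop <- energy(prop)
    acc <- stats::runif(m) < exp((e - e_prop) / kbt)
    state[acc, ] <- prop[acc, , drop = FALSE]
    e[acc] <- e_prop[acc]
  }
  state
}

# Draw n samples by running ceiling(n/per_chain) parallel chains with
# `burn_in` equilibration steps, then taking one draw every `thin` steps.
run_sampler <- function(n, d, energy, kbt, theta0, burn_in = 1000L,
                        thin = 10L, per_chain = 10L, prop_sd = deg2rad(5)) {
  m <- as.integer(ceiling(n / per_chain))
  state <- matrix(theta0, m, d)
  state <- metropolis_chains(state, energy, kbt, burn_in, prop_sd)
  draws <- vector("list", per_chain)
  for (k in seq_len(per_chain)) {
    state <- metropolis_chains(state, energy, kbt, thin, prop_sd)
    draws[[k]] <- state
  }
  out <- do.call(rbind, draws)
  out[seq_len(n), , drop = FALSE]
}

#' Sample stalk-angle pairs of offset dimers from the Boltzmann distribution
#'
#' Draws `(theta_trailing, theta_leading)` pairs from the Boltzmann
#' distribution of the dimer's elastic energy: two independent torsion
#' springs at the stalk-stalkhead hinges plus a linear tether between the
#' stalk bases whose elongation depends on the stalkhead separation and both
#' angles. With the tether off, the two angles are independent and the
#' equipartition theorem fixes their variance at `k_B T / kappa`. With the
#' tether on, larger stalkhead separations stretch the tether, steepening
#' the trailing stalk and shallowing the leading stalk.
#'
#' Sampling is by a vectorized Metropolis random walk (Gaussian proposals,
#' s.d. 5 degrees; 1,000-step burn-in; thinning 10) over many independent
#' chains, validated in the tests against grid quadrature of the density.
#'
#' @param mech A [mechanical_params()] object.
#' @param geom A [motor_geometry()] object.
#' @param lattice_sep Stalkhead separation (nm), normally one of
#'   [separation_classes()].
#' @param n Number of dimers to draw.
#' @param seed Integer seed; draws are reproducible given (params, seed).
#' @return Data frame with columns `theta_trailing` and `theta_leading`
#'   (degrees).
#' @export
sample_offset_dimers <- function(mech, geom, lattice_sep, n, seed) {
  stopifnot(inherits(mech, "mechanical_params"),
            inherits(geom, "motor_geometry"), n >= 1)
  if (lattice_sep < 0)
    stop("lattice_sep must be >= 0", call. = FALSE)
  if (mech$tether_stiffness > 0 &&
      (mech$kappa_trailing <= 0 || mech$kappa_leading <= 0))
    stop("configuration error: non-positive hinge stiffness with nonzero tether",
         call. = FALSE)
  a <- tether_attach_radius(mech, geom)
  energy <- function(s) offset_energy(s[, 1], s[, 2], mech, a, lattice_sep)
  th <- withr::with_seed(seed,
    run_sampler(n, 2L, energy, mech$thermal_energy, deg2rad(mech$rest_angle)))
  data.frame(theta_trailing = rad2deg(th[, 1]),
             theta_leading = rad2deg(th[, 2]))
}

#' Sample stalk angles of superposed dimers
#'
#' Single-angle Boltzmann sampling for the superposed configuration, whose
#' two stacked hinges act as one stiffer torsion spring
#' (`kappa_superposed`).
#'
#' @inheritParams sample_offset_dimers
#' @return Data frame with column `theta` (degrees).
#' @export
sample_superposed_dimers <- function(mech, geom, n, seed) {
  stopifnot(inherits(mech, "mechanical_params"), n >= 1)
  if (mech$kappa_superposed <= 0)
    stop("configuration error: kappa_superposed must be > 0", call. = FALSE)
  th0 <- deg2rad(mech$rest_angle)
  kappa <- mech$kappa_superposed
  energy <- function(s) 0.5 * kappa * (s[, 1] - th0)^2
  # stiffer springs need proportionally finer proposals to keep mixing
  sd_eq <- sqrt(mech$thermal_energy / kappa)
  th <- withr::with_seed(seed,
    run_sampler(n, 1L, energy, mech$thermal_energy, th0,
                prop_sd = min(deg2rad(5), 2 * sd_eq)))
  data.frame(theta = rad2deg(th[, 1]))
}

#' Convert sampled angles into a measured particle table
#'
#' Inverse of the geometric measurement: each motor's ring centre is placed
#' at height `hinge_height + ring_to_hinge * sin(theta)` above the MT
#' surface and axially `ring_to_hinge * cos(theta)` plus-end-ward of its
#' stalkhead, then Gaussian measurement noise is added to both coordinates.
#' With zero noise the table round-trips exactly through [stalk_angle()] and
#' [stalkhead_x()].
#'
#' @param theta Stalk angles (degrees), in (0, 90).
#' @param stalkhead_x Stalkhead axial positions (nm, minus-end positive).
#' @param geom A [motor_geometry()] object.
#' @param noise_sd Measurement noise s.d. (nm) on ring x and height.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param mt_id Microtubule identifier for all rows.
#' @param class_label Classification label for all rows.
#' @return A particle table (data frame) with columns `particle_id`,
#'   `mt_id`, `axial_x_nm` (ring centre), `ring_height_nm`,
#'   `n_rings_visible`, `pixel_sum`, `class_label`.
#' @export
to_particle_table <- function(theta, stalkhead_x, geom = motor_geometry(),
                              noise_sd = 0, seed = NULL, mt_id = "mt1",
                              class_label = "unknown") {
  stopifnot(length(theta) == length(stalkhead_x))
  if (any(theta <= 0 | theta >= 90))
    stop("theta must be in (0, 90) degrees", call. = FALSE)
  th <- deg2rad(theta)
  h <- geom$hinge_height + geom$ring_to_hinge * sin(th)
  x <- stalkhead_x - geom$ring_to_hinge * cos(th)
  n <- length(theta)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, stats::rnorm(2L * n, sd = noise_sd))
    x <- x + noise[seq_len(n)]
    h <- h + noise[n + seq_len(n)]
  }
  data.frame(particle_id = sprintf("p%06d", seq_len(n)),
             mt_id = mt_id, axial_x_nm = x, ring_height_nm = h,
             n_rings_visible = 1L,
             pixel_sum = ifelse(class_label == "superposed", 2, 1),
             class_label = class_label,
             stringsAsFactors = FALSE)
}

#' Place particles along microtubules by a Poisson process
#'
#' @param density Expected particles per 100 nm of microtubule.
#' @param mt_length Microtubule length (nm).
#' @param n_mts Number of microtubules.
#' @param seed Integer seed.
#' @return Data frame with columns `particle_id`, `mt_id`, `axial_x_nm`
#'   (uniform positions, Poisson counts per MT).
#' @export
place_on_mt <- function(density, mt_length, n_mts, seed) {
  stopifnot(density >= 0, mt_length > 0, n_mts >= 1)
  withr::with_seed(seed, {
    counts <- stats::rpois(n_mts, density * mt_length / 100)
    xs <- lapply(counts, function(k) sort(stats::runif(k, 0, mt_length)))
  })
  n_tot <- sum(lengths(xs))
  data.frame(particle_id = sprintf("p%06d", seq_len(max(n_tot, 0))),
             mt_id = rep(sprintf("mt%03d", seq_len(n_mts)), lengths(xs)),
             axial_x_nm = unlist(xs),
             stringsAsFactors = FALSE)[seq_len(n_tot), , drop = FALSE]
}

#' Simulate processive run lengths under the independent-heads model
#'
#' Each mechanical cycle the run terminates if both heads are detached
#' simultaneously, which for independent heads of duty ratio `r` happens
#' with probability `(1 - r)^2`; otherwise the motor completes one step of
#' `step_nm`. The number of completed cycles is geometric, so the run
#' length is `step_nm` times a geometric variate.
#'
#' @param duty_ratio Per-head duty ratio, in (0, 1).
#' @param step_nm Step size (nm).
#' @param n_runs Number of runs to simulate.
#' @param seed Integer seed.
#' @return Numeric vector of run lengths (nm).
#' @export
simulate_runs <- function(duty_ratio, step_nm, n_runs, seed) {
  if (duty_ratio <= 0 || duty_ratio >= 1)
    stop("domain error: duty_ratio must be in (0, 1)", call. = FALSE)
  p_end <- (1 - duty_ratio)^2
  withr::with_seed(seed, stats::rgeom(n_runs, p_end)) * step_nm
}

#' Generate a full synthetic particle data set
#'
#' Draws dimer counts per stalkhead-separation class from
#' `config$separation_weights`, samples angles from the Boltzmann model,
#' converts them to measured particle tables (two rows per offset dimer,
#' one per superposed dimer) and spaces dimers sparsely along synthetic
#' microtubules so the isolation filter can find them.
#'
#' @param config A [gen_config()] object.
#' @param mech A [mechanical_params()] object.
#' @param geom A [motor_geometry()] object.
#' @param lattice A [lattice_params()] object.
#' @param spacing Centre-to-centre spacing between successive dimers along
#'   the synthetic microtubule (nm); the default keeps them isolated under
#'   the 40-nm rule.
#' @return A particle table with `pair_id` and ground-truth columns
#'   (`true_theta_deg`, `true_separation_nm`, `true_role`) appended. The
#'   rare dimer whose sampled angle falls outside the measurable (0, 90)
#'   degree side-view range (well under 1 percent at the default
#'   stiffnesses) is dropped, so slightly fewer than `n_dimers` rows can be
#'   returned.
#' @export
generate_particles <- function(config, mech = mechanical_params(),
                               geom = motor_geometry(),
                               lattice = lattice_params(), spacing = 150) {
  stopifnot(inherits(config, "gen_config"))
  seps <- as.numeric(names(config$separation_weights))
  counts <- withr::with_seed(config$seed,
    as.vector(stats::rmultinom(1, config$n_dimers, config$separation_weights)))
  sup_class <- lattice$pf_stagger  # superposed stalkheads sit one stagger apart
  tables <- list()
  dimer_i <- 0L
  for (ci in seq_along(seps)) {
    n_c <- counts[ci]
    if (n_c == 0L) next
    sep <- seps[ci]
    sub_seed <- config$seed + 1000L * ci
    if (sep <= sup_class + 1e-9) {
      # superposed stalkheads: rings associate with equilibrium constant K,
      # so a fraction K/(K+1) have superposed rings; the rest have offset
      # rings at the same stalkhead separation
      K <- config$assoc_equilibrium
      n_sup <- withr::with_seed(sub_seed + 2L,
                                stats::rbinom(1, n_c, K / (K + 1)))
      if (n_sup > 0) {
        tab <- superposed_subtable(n_sup, sep, mech, geom, config,
                                   sub_seed, spacing, dimer_i)
        dimer_i <- dimer_i + attr(tab, "n_dimers")
        tables[[length(tables) + 1L]] <- tab
      }
      if (n_c - n_sup > 0) {
        tab <- offset_subtable(n_c - n_sup, sep, mech, geom, config,
                               sub_seed + 3L, spacing, dimer_i)
        dimer_i <- dimer_i + attr(tab, "n_dimers")
        tables[[length(tables) + 1L]] <- tab
      }
    } else {
      tab <- offset_subtable(n_c, sep, mech, geom, config, sub_seed,
                             spacing, dimer_i)
      dimer_i <- dimer_i + attr(tab, "n_dimers")
      tables[[length(tables) + 1L]] <- tab
    }
  }
  out <- do.call(rbind, tables)
  out$particle_id <- sprintf("p%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# one block of superposed-ring dimers, spaced along the synthetic MT
superposed_subtable <- function(n, sep, mech, geom, config, seed, spacing,
                                dimer_i) {
  ang <- sample_superposed_dimers(mech, geom, n, seed)
  # the quadratic energy occasionally samples angles outside the
  # measurable side-view range; such dimers would not be picked
  ang <- ang[ang$theta > 0.1 & ang$theta < 89.9, , drop = FALSE]
  n <- nrow(ang)
  base_x <- spacing * (dimer_i + seq_len(n))
  tab <- to_particle_table(ang$theta, base_x, geom,
                           config$measurement_noise_sd, seed + 1L,
                           class_label = "superposed")
  tab$pair_id <- NA_integer_
  tab$true_theta_deg <- ang$theta
  tab$true_separation_nm <- sep
  tab$true_role <- "superposed"
  attr(tab, "n_dimers") <- n
  tab
}

# one block of offset-ring dimers (two rows each) at a fixed separation
offset_subtable <- function(n, sep, mech, geom, config, seed, spacing,
                            dimer_i) {
  ang <- sample_offset_dimers(mech, geom, sep, n, seed)
  keep <- ang$theta_trailing > 0.1 & ang$theta_trailing < 89.9 &
    ang$theta_leading > 0.1 & ang$theta_leading < 89.9
  ang <- ang[keep, , drop = FALSE]
  n <- nrow(ang)
  base_x <- spacing * (dimer_i + seq_len(n))
  theta <- c(rbind(ang$theta_trailing, ang$theta_leading))
  shx <- c(rbind(base_x, base_x + sep))
  tab <- to_particle_table(theta, shx, geom,
                           config$measurement_noise_sd, seed + 1L,
                           class_label = "offset")
  tab$pair_id <- rep(dimer_i + seq_len(n), each = 2L)
  tab$true_theta_deg <- theta
  tab$true_separation_nm <- sep
  tab$true_role <- rep(c("trailing", "leading"), n)
  attr(tab, "n_dimers") <- n
  tab
}
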