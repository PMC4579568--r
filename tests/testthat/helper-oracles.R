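# Independent oracles used across the suite. These deliberately use naive
# formulations (explicit loops, direct quadrature, closed forms) so they
# share no code path with the package implementations they check.

kbt_293 <- 0.0138065 * 293

# Trapezoid quadrature moments of the 1-D Boltzmann density
# exp(-kappa (th - th0)^2 / (2 kbt)), angles in degrees.
quad_moments_1d <- function(kappa, rest_deg, kbt, n_grid = 4001) {
  sd_rad <- sqrt(kbt / kappa)
  th <- seq(deg2rad_o(rest_deg) - 8 * sd_rad, deg2rad_o(rest_deg) + 8 * sd_rad,
            length.out = n_grid)
  w <- exp(-kappa * (th - deg2rad_o(rest_deg))^2 / (2 * kbt))
  w <- w / sum(w)
  m1 <- sum(w * th)
  v <- sum(w * (th - m1)^2)
  list(mean_deg = rad2deg_o(m1), sd_deg = rad2deg_o(sqrt(v)))
}

# Grid quadrature moments of the 2-D offset-dimer Boltzmann density.
# Energy written out directly from the model definition.
quad_moments_2d <- function(mech, attach, lattice_sep, n_grid = 400) {
  th0 <- deg2rad_o(mech$rest_angle)
  sd_t <- sqrt(mech$thermal_energy / mech$kappa_trailing)
  sd_l <- sqrt(mech$thermal_energy / mech$kappa_leading)
  gt <- seq(th0 - 6 * sd_t, th0 + 6 * sd_t, length.out = n_grid)
  gl <- seq(th0 - 6 * sd_l, th0 + 6 * sd_l, length.out = n_grid)
  TT <- matrix(gt, n_grid, n_grid)
  LL <- matrix(gl, n_grid, n_grid, byrow = TRUE)
  elong <- lattice_sep - attach * cos(LL) + attach * cos(TT) -
    mech$tether_rest_separation
  E <- 0.5 * mech$kappa_trailing * (TT - th0)^2 +
    0.5 * mech$kappa_leading * (LL - th0)^2 +
    0.5 * mech$tether_stiffness * elong^2
  w <- exp(-(E - min(E)) / mech$thermal_energy)
  w <- w / sum(w)
  mt <- sum(w * TT); ml <- sum(w * LL)
  list(mean_trail_deg = rad2deg_o(mt), mean_lead_deg = rad2deg_o(ml),
       sd_trail_deg = rad2deg_o(sqrt(sum(w * (TT - mt)^2))),
       sd_lead_deg = rad2deg_o(sqrt(sum(w * (LL - ml)^2))))
}

deg2rad_o <- function(x) x * pi / 180
rad2deg_o <- function(x) x * 180 / pi

# Brute-force O(n^2) isolation filter, straight from the selection rules:
# pairs closer than pair_window with no other head within exclusion of
# either member; singles with nearest neighbour beyond exclusion.
isolate_oracle <- function(particles, pair_window = 40, exclusion = 40) {
  x <- particles$axial_x_nm
  id <- as.character(particles$particle_id)
  n <- length(x)
  pairs <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (abs(x[i] - x[j]) >= pair_window) next
      ok <- TRUE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (abs(x[k] - x[i]) <= exclusion || abs(x[k] - x[j]) <= exclusion) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        a <- if (x[i] <= x[j]) c(i, j) else c(j, i)
        pairs[[length(pairs) + 1]] <- id[a]
      }
    }
  }
  singles <- character(0)
  for (i in seq_len(n)) {
    nn <- Inf
    for (k in seq_len(n)) if (k != i) nn <- min(nn, abs(x[k] - x[i]))
    if (nn > exclusion) singles <- c(singles, id[i])
  }
  singles <- setdiff(singles, unlist(pairs))
  list(pairs = pairs, singles = singles)
}

# Closed-form normal-equation OLS
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Naive per-window recomputation of sliding statistics
running_stats_oracle <- function(x, y, window) {
  n <- length(x)
  out <- data.frame(mean_x = numeric(n - window + 1),
                    mean_y = numeric(n - window + 1),
                    sd_y = numeric(n - window + 1))
  for (i in seq_len(n - window + 1)) {
    idx <- i:(i + window - 1)
    out$mean_x[i] <- mean(x[idx])
    out$mean_y[i] <- mean(y[idx])
    out$sd_y[i] <- sd(y[idx])
  }
  out
}

# Intensity-weighted centroid of an image (x, y in pixel units, 0-based
# pixel centres at integer + 0.5)
centroid_oracle <- function(img) {
  tot <- sum(img)
  xs <- (col(img) - 0.5)
  ys <- (row(img) - 0.5)
  c(x = sum(img * xs) / tot, y = sum(img * ys) / tot)
}

# standard mechanics defaults used in many tests
default_mech <- function(...) mechanical_params(...)
default_geom <- function() motor_geometry()
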