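#' Torsional stiffness of the hinge by the equipartition theorem
#'
#' A torsion spring explored thermally carries `k_B T / 2` of energy, so the
#' observed variance of the stalk angle fixes the spring constant:
#' `kappa = k_B T / sigma^2` with `sigma` in radians.
#'
#' @param sigma Angular standard deviation (degrees).
#' @param thermal_energy `k_B T` (pN nm); 4.045 pN nm at 293 K.
#' @return Torsional stiffness (pN nm rad^-2).
#' @export
torsional_stiffness <- function(sigma, thermal_energy = KB_PN_NM * 293) {
  if (any(sigma <= 0)) stop("domain error: sigma must be > 0", call. = FALSE)
  thermal_energy / deg2rad(sigma)^2
}

#' Apparent cantilever stiffness of an attached motor
#'
#' Resistance of the MT-attached motor to an axial force applied at the
#' base of the stalk. For a rigid lever of length `L` hinged at the
#' stalkhead and inclined at angle `phi` to the MT axis, the effective
#' lever for axial displacement is `L sin(phi)`, hence
#' `k = kappa / (L sin(phi))^2`.
#'
#' @param kappa Torsional stiffness of the hinge (pN nm rad^-2).
#' @param lever Lever length from hinge to stalk base (nm).
#' @param phi Mean stalk angle (degrees), in (0, 90].
#' @return Cantilever stiffness (pN nm^-1).
#' @export
cantilever_stiffness <- function(kappa, lever, phi) {
  if (any(phi <= 0 | phi > 90))
    stop("domain error: phi must be in (0, 90] degrees", call. = FALSE)
  if (any(lever <= 0)) stop("lever must be > 0", call. = FALSE)
  kappa / (lever * sin(deg2rad(phi)))^2
}

#' Equipartition stiffness report for a sample of stalk angles
#'
#' @param theta Stalk angles (degrees).
#' @param geom A [motor_geometry()] object (supplies the lever length).
#' @param thermal_energy `k_B T` (pN nm).
#' @return List of class `stiffness_report`: `sigma_deg`, `kappa`
#'   (pN nm rad^-2), `phi_mean` (deg), `cantilever_k` (pN nm^-1), `n`.
#' @export
stiffness_report <- function(theta, geom = motor_geometry(),
                             thermal_energy = KB_PN_NM * 293) {
  sigma <- stats::sd(theta)  # denominator n - 1
  kappa <- torsional_stiffness(sigma, thermal_energy)
  phi <- mean(theta)
  structure(
    list(sigma_deg = sigma, kappa = kappa, phi_mean = phi,
         cantilever_k = cantilever_stiffness(kappa, geom$lever_length, phi),
         n = length(theta)),
    class = "stiffness_report")
}

#' Ordinary least-squares fit of angle against separation
#'
#' @param x Stalkhead separations (nm).
#' @param y Stalk angles (degrees).
#' @return List of class `regression_fit`: `slope` (deg nm^-1), `intercept`
#'   (deg), `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) < 3L)
    stop("fit error: need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0)
    stop("fit error: zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(x)),
            class = "regression_fit")
}

#' Sliding-window running statistics
#'
#' With data sorted by `x`, computes the mean of `x`, mean of `y` and s.d.
#' of `y` over the first `window` points, then slides the window one point
#' at a time until all points have been included.
#'
#' @param x Sorting variable (e.g. stalkhead separation, nm); must be
#'   non-decreasing.
#' @param y Response (e.g. stalk angle, degrees).
#' @param window Window size (count).
#' @return Data frame with `n - window + 1` rows: `mean_x`, `mean_y`, `sd_y`.
#' @export
running_stats <- function(x, y, window = 100L) {
  n <- length(x)
  if (n < window) stop("size error: n < window", call. = FALSE)
  if (is.unsorted(x)) stop("data must be sorted by x", call. = FALSE)
  data.frame(
    mean_x = zoo::rollapply(x, window, mean),
    mean_y = zoo::rollapply(y, window, mean),
    sd_y = zoo::rollapply(y, window, stats::sd))
}

#' Slope of the pairwise leading-trailing angle difference
#'
#' @param fit_leading,fit_trailing [ols_fit()] results for leading and
#'   trailing motors.
#' @return Difference of slopes (deg nm^-1); negative when the tether pulls
#'   the two stalk angles together with increasing separation.
#' @export
pairwise_difference_slope <- function(fit_leading, fit_trailing) {
  fit_leading$slope - fit_trailing$slope
}

#' Inter-head tension per nm of stalkhead separation
#'
#' Torque balance at the hinge: the axial tether force `T` applied at the
#' stalk base has moment arm `lever * sin(phi)`, and the hinge opposes with
#' torque `kappa * dtheta`. A measured angle response of `slope` (degrees
#' per nm of stalkhead separation) therefore implies a tension growth of
#' `kappa * |slope_rad| / (lever * sin(phi))` pN per nm.
#'
#' @param kappa Torsional stiffness (pN nm rad^-2).
#' @param slope Angle-vs-separation regression slope (deg nm^-1; sign
#'   ignored).
#' @param lever Lever length (nm).
#' @param phi_mean Mean stalk angle (degrees), nonzero.
#' @return Tension per nm of stalkhead separation (pN nm^-1).
#' @export
tension_per_nm <- function(kappa, slope, lever, phi_mean) {
  if (any(phi_mean == 0)) stop("singular: phi_mean = 0", call. = FALSE)
  kappa * abs(deg2rad(slope)) / (lever * sin(deg2rad(phi_mean)))
}

#' Time-averaged tension at a given stalkhead separation
#'
#' @param separation Stalkhead separation (nm).
#' @param per_nm Tension per nm of separation (pN nm^-1).
#' @return Tension (pN).
#' @export
tension_at <- function(separation, per_nm) separation * per_nm

#' Mean ring-centre separation predicted from the angle regressions
#'
#' Each motor's ring lies `ring_to_hinge * cos(theta)` plus-end-ward of its
#' stalkhead, so the mean ring separation at stalkhead separation `x`
#' follows from the two regression lines `theta(x)`. Two conventions are
#' provided:
#'
#' * `"as_published"` - first-order (small-angle-change) linearization
#'   about the regression intercepts:
#'   `x * (1 - L * (sin(b_t) * |m_t| + sin(b_l) * |m_l|)) + L * (cos(b_l) - cos(b_t))`
#'   with slopes in rad nm^-1 and intercepts `b` in degrees. This
#'   reproduces the reported estimates (-0.1, 6.6, 14.2, 21.7 nm at the
#'   four lattice separations).
#' * `"geometric"` - exact evaluation
#'   `x - L * cos(theta_l(x)) + L * cos(theta_t(x))` with the regression
#'   lines; self-consistent with the generator's geometry but differing
#'   from the published linearization by up to ~1 nm (see the methods
#'   vignette). Used in the synthetic-data closure tests.
#'
#' @param stalkhead_sep Stalkhead separation(s) `x` (nm).
#' @param fit_trail,fit_lead [ols_fit()] results for trailing and leading
#'   angles (slopes in deg nm^-1, intercepts in degrees).
#' @param ring_to_hinge Ring-centre-to-hinge distance `L` (nm).
#' @param mode `"as_published"` or `"geometric"`.
#' @return Predicted mean ring-centre separation (nm, signed).
#' @export
ring_sep_from_regressions <- function(stalkhead_sep, fit_trail, fit_lead,
                                      ring_to_hinge = 18.8,
                                      mode = c("as_published", "geometric")) {
  mode <- match.arg(mode)
  L <- ring_to_hinge
  b_t <- fit_trail$intercept; m_t <- fit_trail$slope
  b_l <- fit_lead$intercept; m_l <- fit_lead$slope
  if (mode == "as_published") {
    shrink <- 1 - L * (sin(deg2rad(b_t)) * abs(deg2rad(m_t)) +
                       sin(deg2rad(b_l)) * abs(deg2rad(m_l)))
    stalkhead_sep * shrink + L * (cos(deg2rad(b_l)) - cos(deg2rad(b_t)))
  } else {
    th_t <- deg2rad(b_t + m_t * stalkhead_sep)
    th_l <- deg2rad(b_l + m_l * stalkhead_sep)
    stalkhead_sep - L * cos(th_l) + L * cos(th_t)
  }
}

#' Stiffness of the elastic inter-head linkage
#'
#' All components of the dimer carry the inter-head tension in series, so
#' the tether stiffness is the increment of tension divided by the
#' increment of ring-ring separation between two stalkhead-separation
#' classes.
#'
#' @param tension_increment Increment of tension (pN).
#' @param ring_sep_increment Increment of ring-centre separation (nm),
#'   nonzero.
#' @return Tether stiffness (pN nm^-1).
#' @export
tether_stiffness <- function(tension_increment, ring_sep_increment) {
  if (any(ring_sep_increment == 0))
    stop("singular: zero ring-separation increment", call. = FALSE)
  tension_increment / ring_sep_increment
}

#' Equilibrium constant of the head-head association
#'
#' Ratio of the frequency of superposed rings to offset rings among
#' molecules whose stalkheads are superposed: the unloaded equilibrium
#' constant for head-head association when both motors are bound.
#'
#' @param n_superposed_rings Count of superposed-ring molecules.
#' @param n_offset_rings_superposed_stalkheads Count of offset-ring
#'   molecules with superposed stalkheads, nonzero.
#' @return Dimensionless equilibrium constant.
#' @export
equilibrium_constant <- function(n_superposed_rings,
                                 n_offset_rings_superposed_stalkheads) {
  if (any(n_offset_rings_superposed_stalkheads == 0))
    stop("singular: zero denominator", call. = FALSE)
  n_superposed_rings / n_offset_rings_superposed_stalkheads
}

#' Full mechanics report from a measured dimer table
#'
#' Runs the complete chain on a dimer table (see [dimer_table()]) plus an
#' optional superposed-angle sample: per-role equipartition stiffness,
#' cantilever stiffness, angle-vs-separation regressions, running averages,
#' tension per nm and at the lattice separations, ring-separation
#' estimates, and the tether stiffness from the increments between the
#' first two offset separation classes.
#'
#' @param dimers Dimer table with `theta_lead_deg`, `theta_trail_deg`,
#'   `stalkhead_separation_nm`, `ring_separation_nm`.
#' @param superposed_theta Optional vector of superposed-dimer angles
#'   (degrees).
#' @param geom A [motor_geometry()] object.
#' @param thermal_energy `k_B T` (pN nm).
#' @param separations Stalkhead separations (nm) at which to report
#'   tension and ring separation.
#' @param mode Ring-separation convention, see
#'   [ring_sep_from_regressions()].
#' @param window Running-average window.
#' @return List of class `mechanics_report`.
#' @export
mechanics_report <- function(dimers, superposed_theta = NULL,
                             geom = motor_geometry(),
                             thermal_energy = KB_PN_NM * 293,
                             separations = c(0.9, 8.3, 16.6, 24.9),
                             mode = c("as_published", "geometric"),
                             window = 100L) {
  mode <- match.arg(mode)
  ord <- order(dimers$stalkhead_separation_nm)
  dimers <- dimers[ord, ]
  x <- dimers$stalkhead_separation_nm

  rep_lead <- stiffness_report(dimers$theta_lead_deg, geom, thermal_energy)
  rep_trail <- stiffness_report(dimers$theta_trail_deg, geom, thermal_energy)
  rep_sup <- if (!is.null(superposed_theta))
    stiffness_report(superposed_theta, geom, thermal_energy) else NULL

  fit_lead <- ols_fit(x, dimers$theta_lead_deg)
  fit_trail <- ols_fit(x, dimers$theta_trail_deg)
  run_lead <- if (nrow(dimers) >= window)
    running_stats(x, dimers$theta_lead_deg, window) else NULL
  run_trail <- if (nrow(dimers) >= window)
    running_stats(x, dimers$theta_trail_deg, window) else NULL

  per_nm_lead <- tension_per_nm(rep_lead$kappa, fit_lead$slope,
                                geom$lever_length, rep_lead$phi_mean)
  per_nm_trail <- tension_per_nm(rep_trail$kappa, fit_trail$slope,
                                 geom$lever_length, rep_trail$phi_mean)
  per_nm_mean <- mean(c(per_nm_lead, per_nm_trail))

  tensions <- tension_at(separations, per_nm_mean)
  names(tensions) <- as.character(separations)
  ring_seps <- ring_sep_from_regressions(separations, fit_trail, fit_lead,
                                         geom$ring_to_hinge, mode)
  names(ring_seps) <- as.character(separations)

  offset_idx <- which(separations > 1)
  k_tether <- if (length(offset_idx) >= 2) {
    i1 <- offset_idx[1]; i2 <- offset_idx[2]
    tether_stiffness(tensions[[i2]] - tensions[[i1]],
                     ring_seps[[i2]] - ring_seps[[i1]])
  } else NA_real_

  structure(
    list(leading = rep_lead, trailing = rep_trail, superposed = rep_sup,
         fit_leading = fit_lead, fit_trailing = fit_trail,
         running_leading = run_lead, running_trailing = run_trail,
         pairwise_slope = pairwise_difference_slope(fit_lead, fit_trail),
         tension_per_nm_leading = per_nm_lead,
         tension_per_nm_trailing = per_nm_trail,
         tension_per_nm_mean = per_nm_mean,
         tensions_at = tensions, ring_separations = ring_seps,
         tether_stiffness = k_tether, mode = mode, n = nrow(dimers)),
    class = "mechanics_report")
}
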