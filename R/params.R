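#' Boltzmann constant in pN nm per kelvin
#' @keywords internal
KB_PN_NM <- 0.0138065

#' Rigid-body dimensions of one dynein motor
#'
#' The motor is treated as a rigid body hinged at the stalk-stalkhead
#' junction, which sits `hinge_height` nm above the microtubule surface.
#' The AAA+ ring centre lies `ring_to_hinge` nm from the hinge along the
#' stalk direction. Axial forces transmitted through the inter-head linkage
#' act at the base of the stalk (where the linker ends), at lever radius
#' `lever_length = ring_to_hinge - head_radius` from the hinge.
#'
#' @param ring_to_hinge Ring centre to hinge distance (nm).
#' @param head_radius Radius of the AAA+ ring (nm).
#' @param lever_length Effective lever from hinge to stalk base (nm). Must
#'   equal `ring_to_hinge - head_radius`; supplied explicitly only as a
#'   consistency check.
#' @param hinge_height Height of the hinge above the microtubule surface
#'   (nm). Not directly measurable; the default reproduces the observed mean
#'   ring height of 14.4 nm at the mean stalk angle of 42 degrees
#'   (14.4 - 18.8 sin 42 ~= 1.8 nm).
#' @return An object of class `motor_geometry`.
#' @export
motor_geometry <- function(ring_to_hinge = 18.8, head_radius = 6.5,
                           lever_length = ring_to_hinge - head_radius,
                           hinge_height = 1.8) {
  vals <- c(ring_to_hinge, head_radius, lever_length, hinge_height)
  if (any(vals <= 0)) stop("all motor dimensions must be > 0", call. = FALSE)
  if (abs(lever_length - (ring_to_hinge - head_radius)) > 1e-9)
    stop("lever_length must equal ring_to_hinge - head_radius", call. = FALSE)
  structure(
    list(ring_to_hinge = ring_to_hinge, head_radius = head_radius,
         lever_length = lever_length, hinge_height = hinge_height),
    class = "motor_geometry")
}

#' Mechanical parameters of the dimer model
#'
#' Parameters of the elastic model used by the synthetic-data generator and
#' the mechanics closure tests. Each stalk-stalkhead hinge is a torsion
#' spring of stiffness `kappa_*` (pN nm rad^-2) with rest angle `rest_angle`
#' (degrees); the two heads of an offset dimer are connected by a linear
#' tether of stiffness `tether_stiffness` (pN nm^-1) and rest elongation
#' `tether_rest_separation` (nm), acting axially at radius `tether_attach`
#' nm from the hinge (default: the lever point at the base of the stalk).
#'
#' @param kappa_leading,kappa_trailing,kappa_superposed Torsional stiffness
#'   of the hinge in leading, trailing and superposed moieties
#'   (pN nm rad^-2).
#' @param rest_angle Unstrained stalk angle (degrees).
#' @param tether_stiffness Inter-head linkage stiffness (pN nm^-1).
#' @param tether_rest_separation Tether elongation at zero strain (nm);
#'   0 means the superposed configuration is the relaxed state.
#' @param tether_attach Radial distance from the hinge at which the tether
#'   force acts (nm); `NULL` means use the motor's `lever_length`.
#' @param temperature Absolute temperature (K).
#' @param thermal_energy k_B * temperature (pN nm); checked for consistency
#'   with `temperature` to 0.1 percent.
#' @return An object of class `mechanical_params`.
#' @export
mechanical_params <- function(kappa_leading = 72, kappa_trailing = 71,
                              kappa_superposed = 101, rest_angle = 42,
                              tether_stiffness = 0.035,
                              tether_rest_separation = 0,
                              tether_attach = NULL,
                              temperature = 293,
                              thermal_energy = KB_PN_NM * temperature) {
  ks <- c(kappa_leading, kappa_trailing, kappa_superposed, tether_stiffness)
  if (any(ks < 0)) stop("stiffnesses must be >= 0", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (abs(thermal_energy - KB_PN_NM * temperature) > 1e-3 * thermal_energy)
    stop("thermal_energy inconsistent with temperature (k_B*T)", call. = FALSE)
  structure(
    list(kappa_leading = kappa_leading, kappa_trailing = kappa_trailing,
         kappa_superposed = kappa_superposed, rest_angle = rest_angle,
         tether_stiffness = tether_stiffness,
         tether_rest_separation = tether_rest_separation,
         tether_attach = tether_attach,
         temperature = temperature, thermal_energy = thermal_energy),
    class = "mechanical_params")
}

#' Synthetic-data generation configuration
#'
#' @param n_dimers Number of dimers to generate (> 0).
#' @param seed Integer seed for all stochastic stages.
#' @param separation_weights Named numeric vector mapping lattice separation
#'   (nm, as character names) to probability; must sum to 1. The default
#'   emulates the observed stalkhead-separation histogram: most dimers at
#'   ~8 nm, fewer at ~16 nm, few at ~24 nm, plus the superposed class at
#'   0.9 nm.
#' @param measurement_noise_sd Gaussian noise s.d. added to measured ring
#'   coordinates (nm).
#' @param crowding_density Particles per 100 nm of microtubule for the
#'   placement simulator.
#' @param assoc_equilibrium Head-head association equilibrium constant:
#'   among dimers with superposed stalkheads (the 0.9-nm class), the ratio
#'   of superposed rings to offset rings. The default reflects the
#'   observed ~10:1 preponderance of superposed rings under no load.
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(n_dimers = 1000L, seed = 1L,
                       separation_weights = c("0.9" = 0.45, "8.3" = 0.35,
                                              "16.6" = 0.15, "24.9" = 0.05),
                       measurement_noise_sd = 0.5,
                       crowding_density = 2,
                       assoc_equilibrium = 10) {
  if (n_dimers <= 0) stop("n_dimers must be > 0", call. = FALSE)
  if (abs(sum(separation_weights) - 1) > 1e-8)
    stop("separation_weights must sum to 1", call. = FALSE)
  if (assoc_equilibrium <= 0)
    stop("assoc_equilibrium must be > 0", call. = FALSE)
  structure(
    list(n_dimers = as.integer(n_dimers), seed = as.integer(seed),
         separation_weights = separation_weights,
         measurement_noise_sd = measurement_noise_sd,
         crowding_density = crowding_density,
         assoc_equilibrium = assoc_equilibrium),
    class = "gen_config")
}

#' Enzymatic parameters of the microtubule-activated ATPase
#'
#' @param kcat Maximal ATP turnover per head (s^-1).
#' @param km Michaelis constant for microtubules (uM tubulin dimer).
#' @return An object of class `enzyme_params`.
#' @export
enzyme_params <- function(kcat = 15, km = 2.5) {
  if (kcat <= 0 || km <= 0) stop("kcat and km must be > 0", call. = FALSE)
  structure(list(kcat = kcat, km = km), class = "enzyme_params")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
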