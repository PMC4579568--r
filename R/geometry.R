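#' Stalk angle from ring height by trigonometry
#'
#' The distance from ring centre to the stalk-stalkhead hinge is constant,
#' so the stalk angle of a motor follows from the perpendicular height of
#' its ring centre above the microtubule surface:
#' `theta = asin((ring_height - hinge_height) / ring_to_hinge)`.
#'
#' Measurement noise can push the arcsine argument marginally above 1; an
#' argument in (1, 1 + tol] is clamped to 90 degrees and flagged in the
#' `"clamped"` attribute, while larger arguments are an error.
#'
#' @param ring_height Ring-centre height above the MT surface (nm); must
#'   exceed the hinge height.
#' @param geom A [motor_geometry()] object.
#' @param tol Clamp tolerance on the arcsine argument.
#' @return Stalk angle(s) in degrees, in (0, 90], with a logical attribute
#'   `"clamped"` marking values clamped to 90.
#' @export
stalk_angle <- function(ring_height, geom = motor_geometry(), tol = 0.02) {
  stopifnot(inherits(geom, "motor_geometry"))
  if (any(ring_height <= geom$hinge_height))
    stop("geometry error: ring_height must exceed hinge_height", call. = FALSE)
  arg <- (ring_height - geom$hinge_height) / geom$ring_to_hinge
  if (any(arg > 1 + tol))
    stop("geometry error: ring height exceeds ring_to_hinge reach", call. = FALSE)
  clamped <- arg > 1
  arg[clamped] <- 1
  theta <- rad2deg(asin(arg))
  attr(theta, "clamped") <- clamped
  theta
}

#' Predicted stalkhead position from ring position and stalk angle
#'
#' The stalkhead lies on the microtubule surface, minus-end-ward of the ring
#' (positive axial direction): `stalkhead_x = ring_x + ring_to_hinge *
#' cos(theta)`.
#'
#' @param ring_x Ring-centre axial position (nm, minus-end positive).
#' @param theta Stalk angle (degrees), in (0, 90].
#' @param geom A [motor_geometry()] object.
#' @return Predicted stalkhead axial position (nm).
#' @export
stalkhead_x <- function(ring_x, theta, geom = motor_geometry()) {
  stopifnot(inherits(geom, "motor_geometry"))
  if (any(theta <= 0 | theta > 90))
    stop("domain error: theta must be in (0, 90] degrees", call. = FALSE)
  ring_x + geom$ring_to_hinge * cos(deg2rad(theta))
}

#' Stalkhead and ring separations of a role-assigned dimer
#'
#' @param leading,trailing Lists (or one-row data frames) with elements
#'   `stalkhead_x` and `ring_x`, as returned by [assign_roles()].
#' @return A list with `stalkhead_separation` (nm, >= 0 by the role
#'   definition) and `ring_separation` (nm, signed, trailing to leading;
#'   negative when the stalks cross).
#' @export
dimer_separations <- function(leading, trailing) {
  need <- c("stalkhead_x", "ring_x")
  if (!all(need %in% names(leading)) || !all(need %in% names(trailing)))
    stop("input error: roles unassigned (need stalkhead_x and ring_x)",
         call. = FALSE)
  sep <- leading$stalkhead_x - trailing$stalkhead_x
  if (any(sep < -1e-9))
    stop("input error: leading stalkhead must not trail", call. = FALSE)
  list(stalkhead_separation = as.numeric(sep),
       ring_separation = as.numeric(leading$ring_x - trailing$ring_x))
}

#' Measure a particle table: angles, stalkhead positions
#'
#' Adds `theta_deg` and `stalkhead_x_nm` columns computed from
#' `ring_height_nm` and `axial_x_nm` (the ring centre position).
#' Measurement noise can push a ring height below the hinge or beyond the
#' geometric reach of the stalk; such rows cannot be measured and are
#' dropped (their count is returned in the `"n_dropped"` attribute).
#'
#' @param particles A particle table (see [read_particle_table()]).
#' @param geom A [motor_geometry()] object.
#' @param tol Arcsine clamp tolerance passed to [stalk_angle()].
#' @return The measurable rows with measurement columns appended.
#' @export
measure_particles <- function(particles, geom = motor_geometry(), tol = 0.02) {
  arg <- (particles$ring_height_nm - geom$hinge_height) / geom$ring_to_hinge
  valid <- arg > 0 & arg <= 1 + tol
  if (any(!valid))
    message(sum(!valid), " particle(s) with unmeasurable ring heights dropped")
  particles <- particles[valid, , drop = FALSE]
  theta <- stalk_angle(particles$ring_height_nm, geom, tol)
  particles$theta_deg <- as.numeric(theta)
  particles$theta_clamped <- attr(theta, "clamped")
  particles$stalkhead_x_nm <- stalkhead_x(particles$axial_x_nm,
                                          particles$theta_deg, geom)
  attr(particles, "n_dropped") <- sum(!valid)
  particles
}

#' Pair up measured motors into role-assigned dimer measurements
#'
#' Applies [assign_roles()] to each pair and [dimer_separations()] to the
#' result, yielding one row per dimer.
#'
#' @param pairs A data frame of paired motors with columns `pair_id`,
#'   `theta_deg`, `stalkhead_x_nm`, `axial_x_nm` (two rows per `pair_id`).
#' @return A data frame with one row per dimer: leading/trailing angles and
#'   positions, stalkhead and ring separations, crossed/ambiguous flags.
#' @export
dimer_table <- function(pairs) {
  split_pairs <- split(pairs, pairs$pair_id)
  rows <- lapply(split_pairs, function(p) {
    if (nrow(p) != 2L) stop("input error: a pair must have two motors", call. = FALSE)
    roles <- assign_roles(
      data.frame(particle_id = p$particle_id,
                 stalkhead_x = p$stalkhead_x_nm,
                 ring_x = p$axial_x_nm,
                 theta = p$theta_deg))
    seps <- dimer_separations(roles$leading, roles$trailing)
    data.frame(pair_id = p$pair_id[1],
               theta_lead_deg = roles$leading$theta,
               theta_trail_deg = roles$trailing$theta,
               stalkhead_x_lead_nm = roles$leading$stalkhead_x,
               stalkhead_x_trail_nm = roles$trailing$stalkhead_x,
               stalkhead_separation_nm = seps$stalkhead_separation,
               ring_separation_nm = seps$ring_separation,
               crossed = roles$crossed, ambiguous = roles$ambiguous)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
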