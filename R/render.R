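#' Image parameters for the toy micrograph renderer
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_nm Pixel size (nm per pixel).
#' @param mt_surface_px Image row (0-based, from the top) of the
#'   microtubule surface; the MT band occupies `mt_width_px` rows below it.
#' @param mt_width_px Width of the microtubule band (pixels).
#' @param mt_intensity,ring_intensity,stalk_intensity Added intensities of
#'   the MT band, ring annuli and stalk segments (protein pale, i.e.
#'   positive on a zero-mean background).
#' @param ring_inner_nm Inner radius of the ring annulus (central channel).
#' @param noise_sd Gaussian pixel noise s.d. (0 = noise-free).
#' @return A list of class `image_params`.
#' @export
image_params <- function(width_px = 96L, height_px = 64L, pixel_size_nm = 1,
                         mt_surface_px = 48L, mt_width_px = 12L,
                         mt_intensity = 1, ring_intensity = 1,
                         stalk_intensity = 0.5, ring_inner_nm = 3,
                         noise_sd = 0) {
  structure(as.list(environment()), class = "image_params")
}

#' Render a toy micrograph of motors on a microtubule
#'
#' Draws a side-view projection: the microtubule as a uniform horizontal
#' band, each AAA+ ring as an annulus of outer radius `head_radius`, and
#' each stalk as a line segment from the ring centre to its stalkhead on
#' the MT surface. Intensities are additive (two superposed rings sum to
#' exactly twice one ring) and the background is zero-mean, as in
#' contrast-inverted micrographs where protein is pale.
#'
#' @param particles Data frame with columns `axial_x_nm` (ring centre) and
#'   `ring_height_nm`; optional `theta_deg` and `stalkhead_x_nm` draw the
#'   stalk; optional `n_copies` multiplies a particle's intensity (e.g. 2
#'   for a superposed dimer).
#' @param geom A [motor_geometry()] object.
#' @param params An [image_params()] object.
#' @param seed Seed for pixel noise (only used when `noise_sd > 0`).
#' @return Numeric matrix `height_px x width_px` (row 1 = top).
#' @export
render_micrograph <- function(particles, geom = motor_geometry(),
                              params = image_params(), seed = NULL) {
  stopifnot(inherits(params, "image_params"))
  w <- params$width_px; h <- params$height_px; px <- params$pixel_size_nm
  img <- matrix(0, h, w)
  # pixel-centre coordinates in nm; y measured as height above MT surface
  xc <- (seq_len(w) - 0.5) * px
  yc <- (params$mt_surface_px - (seq_len(h) - 0.5)) * px
  X <- matrix(xc, h, w, byrow = TRUE)
  Y <- matrix(yc, h, w)
  # MT band: rows below the surface
  band <- Y <= 0 & Y > -params$mt_width_px * px
  img[band] <- img[band] + params$mt_intensity
  n_cop <- if ("n_copies" %in% names(particles)) particles$n_copies else
    rep(1, nrow(particles))
  for (i in seq_len(nrow(particles))) {
    cx <- particles$axial_x_nm[i]
    cy <- particles$ring_height_nm[i]
    r2 <- (X - cx)^2 + (Y - cy)^2
    ring <- r2 <= geom$head_radius^2 & r2 >= params$ring_inner_nm^2
    img[ring] <- img[ring] + n_cop[i] * params$ring_intensity
    if (all(c("theta_deg", "stalkhead_x_nm") %in% names(particles))) {
      sx <- particles$stalkhead_x_nm[i]
      # distance from each pixel to the segment (sx, 0) -- (cx, cy)
      vx <- cx - sx; vy <- cy
      len2 <- vx^2 + vy^2
      t_par <- pmin(1, pmax(0, ((X - sx) * vx + Y * vy) / len2))
      d2 <- (X - (sx + t_par * vx))^2 + (Y - t_par * vy)^2
      stalk <- d2 <= 1 & r2 > geom$head_radius^2
      img[stalk] <- img[stalk] + n_cop[i] * params$stalk_intensity
    }
  }
  if (params$noise_sd > 0)
    img <- img + withr::with_seed(seed,
      matrix(stats::rnorm(h * w, sd = params$noise_sd), h, w))
  img
}
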