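#' Microtubule binding-site lattice parameters
#'
#' Geometry of the 14-protofilament, 3-start (14_3) microtubule lattice that
#' fixes the allowed axial separations between stalkhead binding sites.
#' Tubulin dimers repeat every `axial_repeat` nm along a protofilament;
#' adjacent protofilaments are staggered axially by `pf_stagger` nm in a
#' left-handed helix, and the lattice seam adds an extra `seam_extra_offset`
#' nm for dimers straddling it.
#'
#' @param axial_repeat Tubulin-dimer repeat along one protofilament (nm).
#' @param pf_stagger Axial stagger between adjacent protofilaments (nm).
#' @param n_protofilaments Number of protofilaments.
#' @param seam_extra_offset Additional axial offset across the lattice seam
#'   (nm); the seam is treated as a single on/off offset, not by full helical
#'   indexing.
#' @param helix_start Helix start number (3 for the 14_3 lattice).
#' @return An object of class `lattice_params`.
#' @examples
#' lp <- lattice_params()
#' site_axial_offset(3, 0, params = lp)  # 24.9 nm
#' @export
lattice_params <- function(axial_repeat = 8.3, pf_stagger = 0.9,
                           n_protofilaments = 14L, seam_extra_offset = 4.0,
                           helix_start = 3L) {
  if (!(axial_repeat > 0)) stop("axial_repeat must be > 0", call. = FALSE)
  if (pf_stagger < 0 || pf_stagger >= axial_repeat)
    stop("pf_stagger must satisfy 0 <= pf_stagger < axial_repeat", call. = FALSE)
  if (n_protofilaments < 10L)
    stop("n_protofilaments must be >= 10", call. = FALSE)
  structure(
    list(axial_repeat = axial_repeat, pf_stagger = pf_stagger,
         n_protofilaments = as.integer(n_protofilaments),
         seam_extra_offset = seam_extra_offset,
         helix_start = as.integer(helix_start)),
    class = "lattice_params")
}

#' Axial offset between two binding sites on the lattice
#'
#' Axial coordinate difference (nm, positive toward the microtubule minus
#' end, i.e. the stepping direction) between a binding site and another
#' displaced by `dimer_steps` tubulin dimers along the protofilament and
#' `pf_steps` protofilaments around the lattice, optionally crossing the seam.
#'
#' @param dimer_steps Integer number of 8.3-nm tubulin-dimer steps.
#' @param pf_steps Integer number of protofilament steps (each adds one
#'   0.9-nm stagger). `abs(pf_steps)` must be smaller than the number of
#'   protofilaments.
#' @param crosses_seam Does the displacement cross the lattice seam?
#' @param params A [lattice_params()] object.
#' @return Axial offset in nm. Vectorized over the first three arguments.
#' @export
site_axial_offset <- function(dimer_steps, pf_steps, crosses_seam = FALSE,
                              params = lattice_params()) {
  stopifnot(inherits(params, "lattice_params"))
  if (any(abs(pf_steps) >= params$n_protofilaments))
    stop("lattice error: |pf_steps| must be < n_protofilaments", call. = FALSE)
  dimer_steps * params$axial_repeat + pf_steps * params$pf_stagger +
    ifelse(crosses_seam, params$seam_extra_offset, 0)
}

#' Allowed stalkhead separation classes
#'
#' Sorted distinct axial separations available to a dimer whose two
#' stalkheads bind the same or an adjacent protofilament (no seam crossing),
#' up to `max_dimer_steps` tubulin-dimer steps apart. With defaults this
#' contains the separations 0.9, 8.3, 16.6 and 24.9 nm at which bound dimers
#' are observed.
#'
#' @param max_dimer_steps Maximum number of tubulin-dimer steps (>= 0).
#' @inheritParams site_axial_offset
#' @return Strictly increasing numeric vector of separations (nm).
#' @export
separation_classes <- function(max_dimer_steps, params = lattice_params()) {
  if (max_dimer_steps < 0) stop("max_dimer_steps must be >= 0", call. = FALSE)
  grid <- expand.grid(dimer = 0:max_dimer_steps, pf = 0:1)
  offs <- site_axial_offset(grid$dimer, grid$pf, FALSE, params)
  sort(unique(offs))
}
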