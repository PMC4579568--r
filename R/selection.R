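#' Isolate unambiguous dimers and singles on one microtubule
#'
#' Selects, from the heads bound along one microtubule, (a) pairs of heads
#' less than `pair_window` nm apart with no third head within `exclusion` nm
#' of either member in both the plus- and minus-end directions, and (b)
#' single heads whose nearest neighbour is more than `exclusion` nm away.
#' Distances are measured axially (along the microtubule), not Euclidean.
#' The two outputs are disjoint by construction.
#'
#' @param particles Data frame with columns `particle_id` and `axial_x_nm`
#'   for heads sharing one `mt_id`.
#' @param pair_window Maximum head-head separation for a pair (nm).
#' @param exclusion Minimum clearance to any neighbour (nm).
#' @return List with elements `pairs` (data frame: `pair_id`, `particle_id_1`,
#'   `particle_id_2`) and `singles` (vector of particle ids).
#' @export
isolate <- function(particles, pair_window = 40, exclusion = 40) {
  if (anyDuplicated(particles$particle_id))
    stop("input error: duplicated particle_id", call. = FALSE)
  x <- particles$axial_x_nm
  if (any(!is.finite(x)))
    stop("input error: axial positions must be finite", call. = FALSE)
  id <- particles$particle_id
  n <- length(x)

  singles <- character(0)
  p1 <- character(0); p2 <- character(0)
  if (n == 1L) {
    singles <- as.character(id[1])
  } else if (n >= 2L) {
    ord <- order(x)
    x <- x[ord]; id <- id[ord]
    gaps <- diff(x)
    nn <- pmin(c(Inf, gaps), c(gaps, Inf))
    singles <- as.character(id[nn > exclusion])
    # candidate pairs: |dx| < pair_window; keep only those with no third
    # head within `exclusion` of either member (axial distances)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (x[j] - x[i] >= pair_window) break
        others <- x[-c(i, j)]
        clear <- !any(abs(others - x[i]) <= exclusion |
                      abs(others - x[j]) <= exclusion)
        if (clear) {
          p1 <- c(p1, as.character(id[i]))
          p2 <- c(p2, as.character(id[j]))
        }
      }
    }
    # outputs are disjoint: pair members are never reported as singles
    singles <- setdiff(singles, c(p1, p2))
  }
  pairs <- data.frame(pair_id = seq_along(p1),
                      particle_id_1 = p1, particle_id_2 = p2,
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L)
    pairs <- data.frame(pair_id = integer(0), particle_id_1 = character(0),
                        particle_id_2 = character(0))
  list(pairs = pairs, singles = singles)
}

roi_values <- function(image, roi) {
  # roi = c(x, y, width, height), 0-based, half-open; image[row, col] with
  # row = y + 1, col = x + 1
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (x < 0 || y < 0 || x + w > ncol(image) || y + h > nrow(image))
    stop("input error: ROI outside image", call. = FALSE)
  image[(y + 1):(y + h), (x + 1):(x + w)]
}

rois_overlap <- function(a, b) {
  !(a[1] + a[3] <= b[1] || b[1] + b[3] <= a[1] ||
    a[2] + a[4] <= b[2] || b[2] + b[4] <= a[2])
}

#' Background-corrected pixel sum of a particle, normalized to the adjacent MT
#'
#' The mean of the background ROI is subtracted from the whole image (so the
#' background ice has mean zero), then the summed pixel values of the
#' particle ROI are divided by those of the adjacent microtubule ROI. The
#' ratio is invariant to any constant intensity offset.
#'
#' @param image Numeric matrix (row = y + 1, col = x + 1; protein pale,
#'   i.e. positive, on a zero-mean background).
#' @param particle_roi,mt_roi,background_roi Integer ROIs `c(x, y, width,
#'   height)`, 0-based, half-open, mutually non-overlapping.
#' @return Dimensionless ratio sum(particle)/sum(MT).
#' @export
normalized_pixel_sum <- function(image, particle_roi, mt_roi, background_roi) {
  rois <- list(particle_roi, mt_roi, background_roi)
  for (i in 1:2) for (j in (i + 1):3)
    if (rois_overlap(rois[[i]], rois[[j]]))
      stop("input error: ROIs must not overlap", call. = FALSE)
  bg <- mean(roi_values(image, background_roi))
  img <- image - bg
  mt_sum <- sum(roi_values(img, mt_roi))
  if (mt_sum <= 0)
    stop("measurement error: MT ROI sum <= 0 after normalization", call. = FALSE)
  sum(roi_values(img, particle_roi)) / mt_sum
}

#' Classify a head as monomer or superposed dimer by its pixel sum
#'
#' A superposed dimer contains two stacked rings and so carries roughly
#' twice the summed, MT-normalized pixel value of a monomer. The decision
#' threshold sits midway between the expected 1x and 2x (boundary
#' inclusive).
#'
#' @param pixel_sum_ratio MT-normalized pixel sum of the head.
#' @param monomer_reference MT-normalized pixel sum of a known monomer.
#' @param threshold Multiplier of the monomer reference above which (>=) a
#'   head is called a superposed dimer.
#' @return `"superposed_dimer"` or `"monomer"` (vectorized).
#' @export
classify_head_count <- function(pixel_sum_ratio, monomer_reference,
                                threshold = 1.5) {
  if (any(monomer_reference <= 0))
    stop("input error: monomer_reference must be > 0", call. = FALSE)
  ifelse(pixel_sum_ratio >= threshold * monomer_reference,
         "superposed_dimer", "monomer")
}

#' Assign leading and trailing roles within a dimer
#'
#' The leading motor is the one whose *stalkhead* (not ring) is farther
#' toward the microtubule minus end (greater axial position); it is the
#' stalkhead that anchors the motor to the track. With crossed stalks the
#' leading stalkhead can attach to the trailing (low-angle) ring, so ring
#' order and stalkhead order may disagree; `crossed` flags this. Exact
#' stalkhead ties are broken by lower `particle_id` and flagged `ambiguous`.
#'
#' @param motors Data frame with two rows and columns `particle_id`,
#'   `stalkhead_x`, `ring_x` and optionally others (carried through).
#' @return List with `leading` and `trailing` (one-row data frames),
#'   `crossed` and `ambiguous` flags.
#' @export
assign_roles <- function(motors) {
  if (nrow(motors) != 2L)
    stop("input error: assign_roles needs exactly two motors", call. = FALSE)
  ambiguous <- motors$stalkhead_x[1] == motors$stalkhead_x[2]
  if (ambiguous) {
    lead_i <- order(as.character(motors$particle_id))[1]
  } else {
    lead_i <- which.max(motors$stalkhead_x)
  }
  trail_i <- 3L - lead_i
  leading <- motors[lead_i, , drop = FALSE]
  trailing <- motors[trail_i, , drop = FALSE]
  list(leading = leading, trailing = trailing,
       crossed = leading$ring_x < trailing$ring_x,
       ambiguous = ambiguous)
}
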