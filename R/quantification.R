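#' Well-counter cross-calibration
#'
#' The conversion factor between well-counter count rate and activity
#' concentration, derived from replicate counts of a phantom of known
#' concentration: `factor = mean(replicate_counts) / phantom_truth`,
#' in counts s^-1 per kBq/mL.
#'
#' @param conversion_factor Directly supplied factor (cps per kBq/mL), or
#'   `NULL` to derive it from replicates.
#' @param phantom_truth Known phantom activity concentration, kBq/mL.
#' @param replicate_counts Replicate count rates of phantom aliquots,
#'   counts s^-1.
#' @return Object of class `well_counter_calibration`.
#' @export
well_counter_calibration <- function(conversion_factor = NULL,
                                     phantom_truth = NULL,
                                     replicate_counts = NULL) {
  if (is.null(conversion_factor)) {
    if (is.null(phantom_truth) || is.null(replicate_counts)) {
      stop("supply conversion_factor or (phantom_truth, replicate_counts)",
           call. = FALSE)
    }
    conversion_factor <- mean(replicate_counts) / phantom_truth
  }
  if (!is.finite(conversion_factor) || conversion_factor <= 0) {
    stop("calibration error: conversion factor must be > 0", call. = FALSE)
  }
  structure(list(conversion_factor = conversion_factor,
                 phantom_truth = phantom_truth,
                 replicate_counts = replicate_counts),
            class = "well_counter_calibration")
}

#' Convert a well-counter count rate to activity concentration
#'
#' @param counts_per_s Count rate, counts s^-1 (>= 0).
#' @param cal A [well_counter_calibration()].
#' @return Activity concentration, kBq/mL.
#' @export
calibrate <- function(counts_per_s, cal) {
  stopifnot(inherits(cal, "well_counter_calibration"))
  if (any(counts_per_s < 0)) stop("count rate must be >= 0", call. = FALSE)
  counts_per_s / cal$conversion_factor
}

#' Decay-correct an activity concentration
#'
#' Corrects a measurement back to a common reference time:
#' `value * 2^(elapsed / half_life)`.
#'
#' @param value Measured concentration, kBq/mL.
#' @param elapsed Minutes elapsed since the reference time.
#' @param half_life Isotope half-life, minutes; default 109.77 (18F).
#' @return Decay-corrected concentration, kBq/mL.
#' @export
decay_correct <- function(value, elapsed, half_life = 109.77) {
  if (half_life <= 0) stop("half_life must be > 0", call. = FALSE)
  value * 2^(elapsed / half_life)
}

#' Segment a lesion by the 40%-of-maximum threshold
#'
#' Reproduces the standard semiautomatic PET lesion contour: starting from
#' a seed voxel, hill-climb (26-neighbourhood steepest ascent) to the local
#' maximum, threshold the image at `threshold_fraction` of that maximum,
#' and keep the 26-connected component of supra-threshold voxels that
#' contains the maximum.  The threshold is relative, so segmentation is
#' invariant to positive rescaling of the image.
#'
#' @param image 3-D numeric array of activity concentrations, kBq/mL.
#' @param seed_voxel Integer index triple (1-based) inside the lesion.
#' @param voxel_volume Volume of one voxel, mL. Default 0.064
#'   (4 mm isotropic).
#' @param threshold_fraction Fraction of the component-local maximum.
#'   Default 0.40.
#' @return Object of class `roi_measurement`: fields `voxels` (n x 3 index
#'   matrix), `voxel_values` (kBq/mL), `max`, `mean` (kBq/mL), `volume`
#'   (cm^3 = mL) and `voxel_volume`.
#' @export
segment_lesion <- function(image, seed_voxel, voxel_volume = 0.064,
                           threshold_fraction = 0.40) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  seed_voxel <- as.integer(seed_voxel)
  dims <- dim(image)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) || any(seed_voxel > dims)) {
    stop("seed voxel outside the image", call. = FALSE)
  }
  if (image[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <= 0) {
    stop("empty ROI: seed voxel lies on zero background", call. = FALSE)
  }
  peak <- hill_climb(image, seed_voxel)
  thr <- threshold_fraction * image[peak[1], peak[2], peak[3]]
  voxels <- flood_fill(image >= thr, peak)
  vals <- image[voxels]
  roi_measurement(voxels, vals, voxel_volume)
}

#' ROI measurement
#'
#' Voxel-level statistics of a region of interest: `max` and `mean`
#' concentration (kBq/mL) and `volume` (voxel count times voxel volume,
#' cm^3).
#'
#' @param voxels n x 3 integer matrix of voxel indices (may be `NULL` when
#'   only values are known).
#' @param voxel_values Voxel concentrations, kBq/mL.
#' @param voxel_volume Volume of one voxel, mL.
#' @param site Optional site label (e.g. `"lesion"`, `"L1-trabecular"`,
#'   `"femur-cortical"`).
#' @return Object of class `roi_measurement`.
#' @export
roi_measurement <- function(voxels, voxel_values, voxel_volume,
                            site = "lesion") {
  if (length(voxel_values) == 0L) stop("empty ROI", call. = FALSE)
  if (any(voxel_values < 0)) stop("ROI voxel values must be >= 0", call. = FALSE)
  structure(list(voxels = voxels,
                 voxel_values = voxel_values,
                 voxel_volume = voxel_volume,
                 max = max(voxel_values),
                 mean = mean(voxel_values),
                 volume = length(voxel_values) * voxel_volume,
                 site = site),
            class = "roi_measurement")
}

#' @export
print.roi_measurement <- function(x, ...) {
  cat(sprintf("ROI (%s): %d voxels, volume %.2f cm^3, max %.3g, mean %.3g kBq/mL\n",
              x$site, length(x$voxel_values), x$volume, x$max, x$mean))
  invisible(x)
}

# steepest-ascent over the 26-neighbourhood until a local maximum
hill_climb <- function(image, start) {
  dims <- dim(image)
  cur <- start
  repeat {
    best <- cur
    best_val <- image[cur[1], cur[2], cur[3]]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- cur + c(dx, dy, dz)
      if (any(nb < 1L) || any(nb > dims)) next
      v <- image[nb[1], nb[2], nb[3]]
      if (v > best_val) { best_val <- v; best <- nb }
    }
    if (all(best == cur)) return(cur)
    cur <- best
  }
}

# 26-connected component of TRUE voxels containing `start`; returns an
# n x 3 index matrix.  Plain BFS over linear indices.
flood_fill <- function(mask, start) {
  dims <- dim(mask)
  lin <- function(ix) ix[, 1] + dims[1] * (ix[, 2] - 1L) + dims[1] * dims[2] * (ix[, 3] - 1L)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  visited <- array(FALSE, dims)
  queue <- matrix(as.integer(start), ncol = 3)
  visited[queue] <- TRUE
  out <- list(queue)
  while (nrow(queue) > 0L) {
    nxt <- list()
    for (i in seq_len(nrow(queue))) {
      nb <- sweep(offsets, 2L, queue[i, ], `+`)
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0L) next
      keep <- mask[nb] & !visited[nb]
      nb <- nb[keep, , drop = FALSE]
      if (nrow(nb) > 0L) {
        visited[nb] <- TRUE
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    queue <- if (length(nxt)) unique(do.call(rbind, nxt)) else
      matrix(integer(0), ncol = 3)
    if (nrow(queue) > 0L) out[[length(out) + 1L]] <- queue
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("i", "j", "k")
  m
}

#' Standardized uptake value
#'
#' Body-weight-normalized uptake,
#' `SUV = concentration / (injected_activity / body_weight)`, with tissue
#' density taken as 1 g/mL so the result carries g/mL units.
#'
#' @param concentration Tissue activity concentration, kBq/mL.
#' @param injected_activity Injected activity, MBq (> 0).
#' @param body_weight Body weight, kg (> 0).
#' @return SUV, g/mL.
#' @examples
#' suv(10, 200, 70)  # 3.5
#' @export
suv <- function(concentration, injected_activity, body_weight) {
  if (injected_activity <= 0) stop("injected activity must be > 0", call. = FALSE)
  if (body_weight <= 0) stop("body weight must be > 0", call. = FALSE)
  concentration * (body_weight * 1000) / (injected_activity * 1000)
}

#' Static (single-time-point) Patlak estimate of Ki
#'
#' Inverts the Patlak relation at one late time point T:
#' \deqn{K_i = \frac{C_{bone}(T) - V_0 C_p(T)}{\int_0^T C_p\, dt},}
#' where V0 is a population value of the effective distribution volume
#' (the Patlak intercept).  Negative estimates are clipped to 0 by
#' default, with a warning.
#'
#' @param C_bone_T Lesion activity concentration at scan time T, kBq/mL.
#' @param cp_T Plasma concentration at T, kBq/mL.
#' @param integral_cp \eqn{\int_0^T C_p dt}, kBq min/mL (> 0).
#' @param V0 Patlak intercept, unitless (>= 0). Default 0.40 — a
#'   placeholder calibrated against the package's own simulator; see the
#'   methods vignette.
#' @param clip Clip negative estimates to zero? Default TRUE.
#' @return Ki, mL min^-1 mL^-1.
#' @export
static_ki <- function(C_bone_T, cp_T, integral_cp, V0 = 0.40, clip = TRUE) {
  if (any(integral_cp <= 0)) stop("integral of Cp must be > 0", call. = FALSE)
  if (any(V0 < 0)) stop("V0 must be >= 0", call. = FALSE)
  ki <- (C_bone_T - V0 * cp_T) / integral_cp
  if (clip && any(ki < 0)) {
    warning(sum(ki < 0), " negative Ki estimate(s) clipped to 0")
    ki[ki < 0] <- 0
  }
  ki
}
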