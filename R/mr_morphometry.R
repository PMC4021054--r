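#' Physical region of interest on one slice
#'
#' A rectangle in physical millimetres on a single slice (anterior-posterior
#' index). `top_left` is the (vertical, medial-lateral) mm position of the
#' rectangle's corner, measured from the volume origin; the rectangle covers
#' the half-open box `[top_left, top_left + (height, width))` and a pixel
#' belongs to it when its *center* falls inside.
#'
#' @param slice_index 1-based slice index.
#' @param top_left length-2 numeric, mm (vertical, medial-lateral).
#' @param height,width rectangle extents in mm (> 0).
#' @return A `physical_roi` list.
#' @export
physical_roi <- function(slice_index, top_left, height, width) {
  if (height <= 0 || width <= 0) {
    stop("ROI height and width must be > 0", call. = FALSE)
  }
  stopifnot(length(top_left) == 2, slice_index >= 1)
  structure(list(slice_index = as.integer(slice_index),
                 top_left = as.numeric(top_left),
                 height = height, width = width),
            class = "physical_roi")
}

#' Map a physical ROI to pixel indices
#'
#' Returns the pixels of the ROI's slice whose centers fall inside the
#' half-open physical rectangle.
#'
#' @param volume an [image_volume()].
#' @param roi a [physical_roi()].
#' @return A list with `slice_index`, integer vectors `rows` and `cols`, and
#'   `n_pixels`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 1)), spacing = c(0.25, 0.25, 1))
#' roi_to_voxels(v, physical_roi(1, c(0, 0), 1, 1))$n_pixels  # 16
#' @export
roi_to_voxels <- function(volume, roi) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "physical_roi"))
  dims <- dim(volume$voxels)
  if (roi$slice_index < 1 || roi$slice_index > dims[3]) {
    stop("ROI slice_index ", roi$slice_index,
         " outside volume (anterior-posterior axis)", call. = FALSE)
  }
  rr <- centers_in_interval(roi$top_left[1], roi$top_left[1] + roi$height,
                            volume$spacing[1], volume$origin[1])
  cc <- centers_in_interval(roi$top_left[2], roi$top_left[2] + roi$width,
                            volume$spacing[2], volume$origin[2])
  if (rr[1] < 1 || rr[2] > dims[1]) {
    stop("ROI extends beyond the slice on the vertical axis", call. = FALSE)
  }
  if (cc[1] < 1 || cc[2] > dims[2]) {
    stop("ROI extends beyond the slice on the medial-lateral axis",
         call. = FALSE)
  }
  if (rr[2] < rr[1] || cc[2] < cc[1]) {
    stop("ROI footprint contains no pixel centers", call. = FALSE)
  }
  list(slice_index = roi$slice_index,
       rows = seq.int(rr[1], rr[2]), cols = seq.int(cc[1], cc[2]),
       n_pixels = (rr[2] - rr[1] + 1L) * (cc[2] - cc[1] + 1L))
}

roi_pixels <- function(volume, roi) {
  m <- roi_to_voxels(volume, roi)
  as.numeric(volume$voxels[m$rows, m$cols, m$slice_index])
}

#' Calibrate the cortical-bone signal-intensity threshold
#'
#' Pools the pixel intensities of 20 small cortical-bone ROIs
#' (0.69 mm x 0.69 mm each) and derives the global threshold used to classify
#' pixels as bone in [apparent_bvtv()]. The default statistic is the pooled
#' mean over all calibration pixels; `mean_sd` (mean + `k_sd` standard
#' deviations) and `percentile` are available as alternatives.
#'
#' @param volume an [image_volume()] (MR-like, bone dark).
#' @param rois list of exactly 20 [physical_roi()] of 0.69 mm x 0.69 mm
#'   (checked within `size_tol` mm).
#' @param statistic one of `"mean"`, `"mean_sd"`, `"percentile"`.
#' @param k_sd multiplier for `"mean_sd"`.
#' @param probs percentile for `"percentile"`.
#' @param size_tol allowed deviation of ROI extents from 0.69 mm.
#' @return A `threshold_calibration` list: `threshold`, `statistic`,
#'   `per_roi` (tibble with per-ROI pixel counts and means), and the pooled
#'   pixel range.
#' @export
calibrate_cortical_threshold <- function(volume, rois,
                                         statistic = c("mean", "mean_sd",
                                                       "percentile"),
                                         k_sd = 0, probs = 0.5,
                                         size_tol = 0.02) {
  statistic <- match.arg(statistic)
  if (length(rois) != 20) {
    stop("threshold calibration requires exactly 20 ROIs, got ",
         length(rois), call. = FALSE)
  }
  for (roi in rois) {
    if (abs(roi$height - 0.69) > size_tol || abs(roi$width - 0.69) > size_tol) {
      stop("calibration ROIs must be 0.69 mm x 0.69 mm", call. = FALSE)
    }
  }
  px <- lapply(rois, function(roi) roi_pixels(volume, roi))
  if (any(lengths(px) == 0)) {
    stop("calibration ROI with empty pixel footprint", call. = FALSE)
  }
  pooled <- unlist(px)
  threshold <- switch(statistic,
    mean = mean(pooled),
    mean_sd = mean(pooled) + k_sd * sd(pooled),
    percentile = unname(quantile(pooled, probs))
  )
  per_roi <- tibble::tibble(
    roi = seq_along(rois),
    slice_index = vapply(rois, `[[`, integer(1), "slice_index"),
    n_pixels = lengths(px),
    mean_intensity = vapply(px, mean, numeric(1))
  )
  structure(
    list(threshold = threshold, statistic = statistic, per_roi = per_roi,
         pixel_range = range(pooled), n_pixels = length(pooled)),
    class = "threshold_calibration"
  )
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat("<threshold_calibration> threshold ", signif(x$threshold, 5),
      " (", x$statistic, " of ", x$n_pixels, " pixels in 20 ROIs)\n",
      sep = "")
  invisible(x)
}

#' Standardized ROI stack on the central slices
#'
#' Places an identically positioned rectangle on the `n_slices` consecutive
#' slices centered on the volume's mid-slice. When the number of spare slices
#' is odd the stack is shifted toward the lower slice index.
#'
#' @param volume an [image_volume()].
#' @param anchor length-2 mm position (vertical, medial-lateral) of the
#'   rectangle's top-left corner. The anatomical placement (immediately below
#'   the articular cartilage) is the caller's responsibility.
#' @param height_mm,width_mm rectangle extents in mm; defaults 3.75 and 15.00.
#' @param n_slices number of consecutive central slices (default 20).
#' @return List of `n_slices` [physical_roi()].
#' @export
central_roi_stack <- function(volume, anchor = c(0, 0), height_mm = 3.75,
                              width_mm = 15.00, n_slices = 20) {
  stopifnot(inherits(volume, "image_volume"))
  n_avail <- dim(volume$voxels)[3]
  if (n_avail < n_slices) {
    stop("volume has ", n_avail, " slices but ", n_slices, " were requested",
         call. = FALSE)
  }
  first <- (n_avail - n_slices) %/% 2 + 1L
  lapply(seq.int(first, first + n_slices - 1L), function(sl) {
    physical_roi(sl, anchor, height_mm, width_mm)
  })
}

#' MR apparent bone volume fraction
#'
#' For each ROI (one per analyzed slice) the apparent BV/TV is the number of
#' pixels with signal intensity at or below the cortical-bone threshold
#' (inclusive comparison) divided by the total number of pixels within the
#' ROI; the per-slice fractions are then averaged.
#'
#' @param volume an [image_volume()] (bone dark).
#' @param rois list of [physical_roi()], one per analyzed slice.
#' @param threshold scalar intensity threshold, or a `threshold_calibration`.
#' @return A `morphometry_result`: `per_slice` tibble (slice index, pixel
#'   count, fraction), `mean_bvtv`, `mean_bvtv_percent`, `threshold` and an
#'   ROI geometry snapshot. [tidy()] returns the per-slice tibble, [glance()]
#'   a one-row summary.
#' @export
apparent_bvtv <- function(volume, rois, threshold) {
  if (inherits(threshold, "threshold_calibration")) {
    threshold <- threshold$threshold
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (length(rois) < 1) stop("need at least one ROI", call. = FALSE)
  per <- purrr::map(rois, function(roi) {
    px <- roi_pixels(volume, roi)
    tibble::tibble(slice_index = roi$slice_index, n_pixels = length(px),
                   bvtv = mean(px <= threshold))
  })
  per_slice <- dplyr::bind_rows(per)
  mean_bvtv <- mean(per_slice$bvtv)
  structure(
    list(per_slice = per_slice, mean_bvtv = mean_bvtv,
         mean_bvtv_percent = 100 * mean_bvtv, threshold = threshold,
         roi_height = rois[[1]]$height, roi_width = rois[[1]]$width,
         n_slices = length(rois)),
    class = "morphometry_result"
  )
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat("<morphometry_result> apparent BV/TV ",
      signif(x$mean_bvtv_percent, 4), "% (mean of ", x$n_slices,
      " slices, threshold ", signif(x$threshold, 5), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.morphometry_result <- function(x, ...) x$per_slice

#' @export
glance.morphometry_result <- function(x, ...) {
  tibble::tibble(mean_bvtv = x$mean_bvtv,
                 mean_bvtv_percent = x$mean_bvtv_percent,
                 threshold = x$threshold, n_slices = x$n_slices,
                 roi_height_mm = x$roi_height, roi_width_mm = x$roi_width)
}

#' Build a grid of cortical calibration ROIs
#'
#' Lays out `n` non-overlapping 0.69 mm x 0.69 mm ROIs row-major inside a
#' rectangular region of the given slices, for use with
#' [calibrate_cortical_threshold()].
#'
#' @param volume an [image_volume()].
#' @param n number of ROIs (default 20).
#' @param top_left mm corner of the layout region (vertical, medial-lateral).
#' @param slice_indices slices over which ROIs are distributed (recycled).
#' @param gap_mm spacing between ROI corners (default 0.69, edge to edge).
#' @return List of `n` [physical_roi()].
#' @export
calibration_roi_grid <- function(volume, n = 20, top_left = c(0, 0),
                                 slice_indices = 1L, gap_mm = 0.69) {
  dims <- dim(volume$voxels)
  ext <- volume_extent(volume)
  per_row <- max(1L, floor((ext[2] - top_left[2]) / gap_mm))
  rois <- vector("list", n)
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% per_row
    cl <- (i - 1L) %% per_row
    sl <- slice_indices[((i - 1L) %% length(slice_indices)) + 1L]
    rois[[i]] <- physical_roi(sl,
                              c(top_left[1] + r * gap_mm,
                                top_left[2] + cl * gap_mm),
                              0.69, 0.69)
  }
  rois
}

#' Calibrate a threshold from a synthetic cortical-bone volume
#'
#' The cadaveric protocol samples thick femoral cortical bone, a structure the
#' trabecular phantom does not contain; this helper emulates it by rendering
#' an all-bone block with the same MR settings and calibrating the threshold
#' on 20 ROIs placed inside it.
#'
#' Every voxel of an all-bone block has bone partial-volume fraction 1, so
#' the block is constructed directly at MR resolution and only the Rician
#' noise model acts on it.
#'
#' @param mr an [mr_render_spec()] shared with the specimens being measured.
#' @param extent mm extent of the cortical block (vertical, medial-lateral,
#'   anterior-posterior).
#' @param seed RNG seed for the calibration rendering.
#' @param ... passed on to [calibrate_cortical_threshold()].
#' @return A `threshold_calibration`.
#' @export
synthetic_cortical_calibration <- function(mr = mr_render_spec(),
                                           extent = c(3, 8, 3), seed = 1L,
                                           ...) {
  dims <- pmax(1L, round(extent / mr$mr_spacing))
  truth <- binary_volume(array(TRUE, dims), mr$mr_spacing)
  vol <- render_mr(truth, mr, seed = sub_seed(seed, 3))
  rois <- calibration_roi_grid(vol, n = 20, top_left = c(0.1, 0.1),
                               slice_indices = seq_len(dim(vol$voxels)[3]))
  calibrate_cortical_threshold(vol, rois, ...)
}
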