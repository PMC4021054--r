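#' 3D image and binary volumes
#'
#' `image_volume()` wraps a 3D scalar voxel grid together with its physical
#' geometry; `binary_volume()` does the same for a boolean bone/background
#' mask. All physical quantities are in millimetres.
#'
#' Axis convention used throughout the package (array dimension order):
#' 1. rows: vertical (superior at row 1),
#' 2. columns: medial-lateral,
#' 3. slices: anterior-posterior (the MR slice axis).
#'
#' Voxel `i` along an axis with spacing `s` covers the half-open physical
#' interval `[origin + (i-1)*s, origin + i*s)`; its center sits at
#' `origin + (i - 1/2)*s`. All region-of-interest and volume-of-interest
#' membership tests in the package use the voxel/pixel *center*.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per axis (all > 0).
#' @param origin numeric length-3, mm position of the corner of voxel
#'   (1,1,1). Default `c(0, 0, 0)`.
#' @param intensity_range declared intensity range, length-2 numeric; defaults
#'   to the observed range.
#' @return An object of class `image_volume` (resp. `binary_volume`).
#' @examples
#' v <- image_volume(array(0, c(4, 4, 2)), spacing = c(0.25, 0.25, 1))
#' dim(v$voxels)
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         intensity_range = NULL) {
  voxels <- as_voxel_array(voxels)
  spacing <- check_spacing(spacing)
  stopifnot(length(origin) == 3, is.finite(origin))
  if (!all(is.finite(voxels))) {
    stop("image_volume: all voxel values must be finite", call. = FALSE)
  }
  if (is.null(intensity_range)) intensity_range <- range(voxels)
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         intensity_range = as.numeric(intensity_range)),
    class = "image_volume"
  )
}

#' @param mask 3D logical array, `TRUE` = bone.
#' @rdname image_volume
#' @export
binary_volume <- function(mask, spacing, origin = c(0, 0, 0)) {
  mask <- as_voxel_array(mask)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop("binary_volume: mask must be logical or 0/1", call. = FALSE)
    }
    mask <- array(as.logical(mask), dim(mask))
  }
  spacing <- check_spacing(spacing)
  structure(
    list(mask = mask, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "binary_volume"
  )
}

as_voxel_array <- function(x) {
  if (is.null(dim(x))) stop("expected a 3D array", call. = FALSE)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3 || any(dim(x) < 1)) {
    stop("expected a non-empty 3D array", call. = FALSE)
  }
  x
}

check_spacing <- function(spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  }
  spacing
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  intensity range [", signif(x$intensity_range[1], 4), ", ",
      signif(x$intensity_range[2], 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat("<binary_volume> ", paste(dim(x$mask), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  bone fraction ", signif(mean(x$mask), 4), "\n", sep = "")
  invisible(x)
}

#' Physical extent of a volume (mm per axis)
#' @param volume an `image_volume` or `binary_volume`.
#' @return numeric length-3 extent in mm.
#' @export
volume_extent <- function(volume) {
  dim(volume_array(volume)) * volume$spacing
}

volume_array <- function(volume) {
  if (inherits(volume, "image_volume")) volume$voxels
  else if (inherits(volume, "binary_volume")) volume$mask
  else stop("expected an image_volume or binary_volume", call. = FALSE)
}

#' Permute the axes of a volume
#'
#' Reorders array dimensions and the spacing/origin components together, so
#' the physical object is unchanged.
#'
#' @param volume an `image_volume` or `binary_volume`.
#' @param perm integer permutation of `1:3`.
#' @return volume of the same class with permuted axes.
#' @export
permute_volume <- function(volume, perm) {
  stopifnot(identical(sort(as.integer(perm)), 1:3))
  arr <- aperm(volume_array(volume), perm)
  if (inherits(volume, "image_volume")) {
    image_volume(arr, volume$spacing[perm], volume$origin[perm],
                 volume$intensity_range)
  } else {
    binary_volume(arr, volume$spacing[perm], volume$origin[perm])
  }
}

# 1-based index range of voxels whose centers fall in the half-open physical
# interval [from, to) along one axis with spacing s and axis origin o. May
# extend beyond the grid; callers are responsible for bounds checks. A small
# epsilon guards against representation error at exact boundaries.
centers_in_interval <- function(from, to, s, o) {
  eps <- 1e-9
  i0 <- ceiling((from - o) / s + 0.5 - eps)
  i1 <- ceiling((to - o) / s + 0.5 - eps) - 1
  c(as.integer(i0), as.integer(i1))
}
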