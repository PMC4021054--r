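#' Read and write volumes
#'
#' NIfTI files carry the voxel spacing in their header and are the primary
#' interchange format; 8-bit multi-page TIFF stacks of axial slices (pages
#' along the vertical axis) are supported for microCT-style data, with the
#' spacing supplied out of band.
#'
#' @param volume an [image_volume()] or [binary_volume()] (masks are written
#'   as 0/1).
#' @param path file path (`.nii` / `.nii.gz`, or `.tif` / `.tiff`).
#' @return `write_*` return `path` invisibly; `read_*` return an
#'   [image_volume()].
#' @name volume_io
NULL

#' @rdname volume_io
#' @export
write_volume_nifti <- function(volume, path) {
  arr <- volume_array(volume)
  if (is.logical(arr)) arr <- array(as.numeric(arr), dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_volume_nifti <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI volume ",
                                           path, ": ", conditionMessage(e),
                                           call. = FALSE))
  arr <- array(as.numeric(img), dim(img))
  image_volume(arr, RNifti::pixdim(img)[1:3])
}

#' @rdname volume_io
#' @export
write_volume_tiff <- function(volume, path) {
  arr <- volume_array(volume)
  if (is.logical(arr)) arr <- array(255 * as.numeric(arr), dim(arr))
  if (min(arr) < 0 || max(arr) > 255) {
    stop("TIFF export expects 8-bit intensities in [0, 255]", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @param spacing mm per axis for the TIFF stack (not stored in the file).
#' @rdname volume_io
#' @export
read_volume_tiff <- function(path, spacing) {
  if (!file.exists(path)) stop("no such volume file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- round(255 * pages[[i]])
  image_volume(arr, spacing, intensity_range = c(0, 255))
}

#' Bundled cadaveric BV/TV dataset
#'
#' Ten paired BV/TV measurements (five donors, both knees, medial tibia):
#' microCT BV/TV and MR apparent BV/TV in percent, with donor demographics.
#' This is the reference dataset the package's agreement statistics are
#' validated against.
#'
#' @param check_digest verify the file against the recorded MD5 of the
#'   bundled dataset and warn on mismatch.
#' @param path optional path to a copy of the dataset; defaults to the
#'   bundled file.
#' @return Tibble with columns `id`, `cadaver`, `side`, `age`, `sex`,
#'   `height_m`, `weight_kg`, `microct_bvtv_percent`, `mr_bvtv_percent`.
#' @export
load_cadaver_bvtv <- function(check_digest = TRUE, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cadaver_bvtv.csv", package = "bvtvtools",
                        mustWork = TRUE)
  }
  if (check_digest) {
    meta <- cadaver_bvtv_meta()
    digest <- unname(tools::md5sum(path))
    if (!identical(digest, meta$md5)) {
      warning("cadaver_bvtv.csv digest mismatch: expected ", meta$md5,
              ", found ", digest, call. = FALSE)
    }
  }
  readr::read_csv(path, show_col_types = FALSE)
}

cadaver_bvtv_meta <- function() {
  jsonlite::read_json(system.file("extdata", "cadaver_bvtv_meta.json",
                                  package = "bvtvtools", mustWork = TRUE),
                      simplifyVector = TRUE)
}
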