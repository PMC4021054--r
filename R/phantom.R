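#' Phantom specification
#'
#' Describes a synthetic trabecular-bone specimen: a ground-truth binary
#' microstructure on a fine isotropic grid with a prescribed bone volume
#' fraction, topped by a pure-bone subchondral cortical plate.
#'
#' The microstructure is a smooth Gaussian random field thresholded at the
#' empirical quantile `1 - target_bvtv` of its own values, which pins the
#' realized trabecular bone fraction to `target_bvtv` up to one voxel of
#' quantile granularity. The plate sits on the superior face (row 1 side) and
#' is excluded from the trabecular-fraction accounting.
#'
#' The default geometry is a desk-scale stand-in for a micro-CT acquisition:
#' a 4 (vertical) x 10 (medial-lateral) x 10 (anterior-posterior) mm volume
#' of interest at 0.05 mm isotropic fine spacing, preserving the qualitative
#' MR : CT resolution ratio of the real modalities while staying computable.
#'
#' @param target_bvtv prescribed trabecular bone volume fraction in `[0, 1]`.
#' @param trabecular_scale correlation length of the microstructure in mm
#'   (default 0.3 mm, conventional trabecular spacing). The smoothing kernel
#'   standard deviation is `trabecular_scale / 2`, so the field autocorrelation
#'   drops to `1/e` at this distance.
#' @param voi_extent mm extent of the trabecular volume of interest per axis
#'   `(vertical, medial-lateral, anterior-posterior)`; the plate is appended on
#'   top of this.
#' @param fine_spacing isotropic fine grid spacing in mm.
#' @param cortical_plate_thickness pure-bone plate thickness in mm (>= 0).
#' @param superior_margin mm of signal-bearing soft tissue (cartilage/marrow)
#'   above the plate (>= 0, default 0.3). Imaging grids are never aligned
#'   with anatomy; this offset keeps the plate boundaries off the MR voxel
#'   boundaries so plate voxels are partial-volume mixed, as they are in real
#'   acquisitions.
#' @param seed integer RNG seed; identical spec implies bit-identical output.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(target_bvtv,
                         trabecular_scale = 0.3,
                         voi_extent = c(4, 10, 10),
                         fine_spacing = 0.05,
                         cortical_plate_thickness = 0.4,
                         superior_margin = 0.3,
                         seed = 1L) {
  if (!is.numeric(target_bvtv) || length(target_bvtv) != 1 ||
      is.na(target_bvtv) || target_bvtv < 0 || target_bvtv > 1) {
    stop("target_bvtv must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(voi_extent)) || any(voi_extent <= 0) ||
      length(voi_extent) != 3) {
    stop("voi_extent must be 3 positive extents (mm)", call. = FALSE)
  }
  if (!is.finite(fine_spacing) || fine_spacing <= 0) {
    stop("fine_spacing must be > 0", call. = FALSE)
  }
  if (!is.finite(trabecular_scale) || trabecular_scale <= 0) {
    stop("trabecular_scale must be > 0", call. = FALSE)
  }
  if (!is.finite(cortical_plate_thickness) || cortical_plate_thickness < 0) {
    stop("cortical_plate_thickness must be >= 0", call. = FALSE)
  }
  if (!is.finite(superior_margin) || superior_margin < 0) {
    stop("superior_margin must be >= 0", call. = FALSE)
  }
  structure(
    list(target_bvtv = target_bvtv,
         trabecular_scale = trabecular_scale,
         voi_extent = as.numeric(voi_extent),
         fine_spacing = fine_spacing,
         cortical_plate_thickness = cortical_plate_thickness,
         superior_margin = superior_margin,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' MicroCT rendering specification
#'
#' Intensity model for the high-resolution bright-bone modality: bone and
#' marrow voxels are drawn around their mean 8-bit gray values with additive
#' Gaussian noise, rounded to integers and clipped to `[0, 255]`.
#'
#' @param bone_gray mean bone intensity (default 180).
#' @param marrow_gray mean marrow intensity (default 40).
#' @param noise_sigma Gaussian noise standard deviation in gray levels.
#' @return A `microct_render_spec` list.
#' @export
microct_render_spec <- function(bone_gray = 180, marrow_gray = 40,
                                noise_sigma = 5) {
  if (!(0 <= marrow_gray && marrow_gray < bone_gray && bone_gray <= 255)) {
    stop("need 0 <= marrow_gray < bone_gray <= 255", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(bone_gray = bone_gray, marrow_gray = marrow_gray,
                 noise_sigma = noise_sigma),
            class = "microct_render_spec")
}

#' MR rendering specification
#'
#' Forward model of the low-resolution dark-bone modality: each MR voxel's
#' bone partial-volume fraction `f` is the block average of the fine binary
#' truth, the noiseless signal is `f * bone_signal + (1 - f) * marrow_signal`
#' (bone gives no signal on this sequence, so bone is dark), and Rician noise
#' is applied as the magnitude of a complex Gaussian perturbation. Optional
#' lesion boxes multiply the local marrow signal before mixing, emulating
#' hyperintense marrow-lesion regions.
#'
#' The default voxel grid is anisotropic, 0.25 mm in-plane (rows/columns) by
#' 1 mm through-plane (slices): the scaled stand-in for a 0.23 x 0.23 x 1 mm
#' clinical acquisition, chosen so each MR voxel tiles an integer block of the
#' default 0.05 mm fine grid.
#'
#' @param bone_signal mean bone intensity, arbitrary units (default 20).
#' @param marrow_signal mean marrow intensity (default 200; must exceed
#'   `bone_signal`).
#' @param mr_spacing mm per axis `(vertical, medial-lateral,
#'   anterior-posterior)`; every component must be an integer multiple of the
#'   truth's fine spacing.
#' @param rician_sigma Rician noise scale in signal units (default 10).
#' @param lesions optional list of lesion boxes, each a list with elements
#'   `lo`, `hi` (mm corners, length-3) and `factor` (> 0) multiplying the
#'   marrow signal for MR voxels whose centers fall inside the box.
#' @return An `mr_render_spec` list.
#' @export
mr_render_spec <- function(bone_signal = 20, marrow_signal = 200,
                           mr_spacing = c(0.25, 0.25, 1),
                           rician_sigma = 10, lesions = NULL) {
  if (!(bone_signal < marrow_signal)) {
    stop("bone_signal must be below marrow_signal (bone is dark)",
         call. = FALSE)
  }
  mr_spacing <- check_spacing(mr_spacing)
  if (rician_sigma < 0) stop("rician_sigma must be >= 0", call. = FALSE)
  for (les in lesions) {
    if (!all(c("lo", "hi", "factor") %in% names(les)) ||
        les$factor <= 0 || any(les$hi < les$lo)) {
      stop("each lesion needs lo <= hi (mm) and factor > 0", call. = FALSE)
    }
  }
  structure(list(bone_signal = bone_signal, marrow_signal = marrow_signal,
                 mr_spacing = mr_spacing, rician_sigma = rician_sigma,
                 lesions = lesions),
            class = "mr_render_spec")
}

#' Generate the ground-truth trabecular microstructure
#'
#' Draws white Gaussian noise on the fine grid of the trabecular VOI, smooths
#' it with a separable Gaussian kernel (correlation length
#' `spec$trabecular_scale`), and keeps the top `target_bvtv` quantile of voxels
#' as bone, so the realized fraction is exact to within one voxel. A pure-bone
#' cortical plate of the requested thickness is appended on the superior face
#' and excluded from the fraction accounting.
#'
#' @param spec a [phantom_spec()].
#' @return A [binary_volume()] with attributes `plate_rows` (fine rows
#'   occupied by the plate) and `true_bvtv` (realized trabecular fraction).
#' @examples
#' truth <- generate_microstructure(phantom_spec(0.3, voi_extent = c(2, 3, 3)))
#' attr(truth, "true_bvtv")
#' @export
generate_microstructure <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$fine_spacing
  n_trab <- round(spec$voi_extent[1] / s)
  n_ml <- round(spec$voi_extent[2] / s)
  n_ap <- round(spec$voi_extent[3] / s)
  n_plate <- round(spec$cortical_plate_thickness / s)
  n_margin <- round(spec$superior_margin / s)
  if (n_trab < 1 || n_ml < 1 || n_ap < 1) {
    stop("voi_extent too small for fine_spacing", call. = FALSE)
  }

  trab <- withr::with_seed(spec$seed, {
    field <- array(rnorm(n_trab * n_ml * n_ap), c(n_trab, n_ml, n_ap))
    sig_vox <- (spec$trabecular_scale / 2) / s
    field <- cpp_gaussian_smooth(field, dim(field), rep(sig_vox, 3))
    threshold_top_fraction(field, spec$target_bvtv)
  })

  mask <- array(FALSE, c(n_margin + n_plate + n_trab, n_ml, n_ap))
  if (n_plate > 0) mask[n_margin + seq_len(n_plate), , ] <- TRUE
  mask[n_margin + n_plate + seq_len(n_trab), , ] <- trab

  out <- binary_volume(mask, rep(s, 3))
  attr(out, "margin_rows") <- n_margin
  attr(out, "plate_rows") <- n_plate
  attr(out, "true_bvtv") <- mean(trab)
  out
}

# Keep exactly round(p * n) of the largest values (ties broken by index).
threshold_top_fraction <- function(field, p) {
  n <- length(field)
  k <- round(p * n)
  mask <- array(FALSE, dim(field))
  if (k == 0) return(mask)
  if (k == n) return(!mask)
  v <- as.numeric(field)
  thr <- -sort(-v, partial = k)[k]  # k-th largest
  mask[field > thr] <- TRUE
  short <- k - sum(mask)
  if (short > 0) mask[which(field == thr)[seq_len(short)]] <- TRUE
  mask
}

#' Render a microCT-like volume from a binary truth
#'
#' @param truth a [binary_volume()] at fine spacing.
#' @param render a [microct_render_spec()].
#' @param seed integer RNG seed for the noise draw.
#' @return An [image_volume()] with 8-bit intensities (bone bright) and the
#'   truth's spacing.
#' @export
render_microct <- function(truth, render = microct_render_spec(), seed = 1L) {
  stopifnot(inherits(truth, "binary_volume"),
            inherits(render, "microct_render_spec"))
  vals <- render$marrow_gray +
    (render$bone_gray - render$marrow_gray) * as.numeric(truth$mask)
  if (render$noise_sigma > 0) {
    vals <- vals + withr::with_seed(
      seed, rnorm(length(vals), sd = render$noise_sigma))
  }
  vals <- round(vals)
  vals[vals < 0] <- 0
  vals[vals > 255] <- 255
  dim(vals) <- dim(truth$mask)
  image_volume(vals, truth$spacing, truth$origin, intensity_range = c(0, 255))
}

#' Render an MR-like volume from a binary truth
#'
#' Implements the partial-volume forward model: block-averages the truth to
#' the coarse MR grid, mixes bone/marrow signals by the bone fraction, applies
#' lesion boxes, then Rician noise. The fine grid is cropped (from the
#' high-index side) to the largest subgrid tiled exactly by MR voxels.
#'
#' @param truth a [binary_volume()] at fine spacing.
#' @param render an [mr_render_spec()].
#' @param seed integer RNG seed for the noise draw.
#' @return An [image_volume()] on the MR grid (bone dark).
#' @export
render_mr <- function(truth, render = mr_render_spec(), seed = 1L) {
  stopifnot(inherits(truth, "binary_volume"),
            inherits(render, "mr_render_spec"))
  ratio <- render$mr_spacing / truth$spacing
  fac <- round(ratio)
  if (any(fac < 1) || any(abs(ratio - fac) > 0.01)) {
    stop("mr_spacing components must be integer multiples of the fine spacing",
         call. = FALSE)
  }
  dims <- dim(truth$mask)
  keep <- (dims %/% fac) * fac
  if (any(keep < fac)) stop("truth grid smaller than one MR voxel",
                            call. = FALSE)
  mask <- truth$mask[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                     drop = FALSE]
  f <- cpp_block_mean(array(as.numeric(mask), dim(mask)), dim(mask),
                      as.integer(fac))

  marrow <- array(render$marrow_signal, dim(f))
  sp <- fac * truth$spacing
  for (les in render$lesions) {
    idx <- lapply(1:3, function(ax) {
      rng <- centers_in_interval(les$lo[ax], les$hi[ax], sp[ax],
                                 truth$origin[ax])
      seq.int(max(1L, rng[1]), min(dim(f)[ax], rng[2]))
    })
    if (all(lengths(idx) > 0)) {
      marrow[idx[[1]], idx[[2]], idx[[3]]] <-
        marrow[idx[[1]], idx[[2]], idx[[3]]] * les$factor
    }
  }

  signal <- f * render$bone_signal + (1 - f) * marrow
  if (render$rician_sigma > 0) {
    signal <- withr::with_seed(seed, {
      g1 <- rnorm(length(signal), sd = render$rician_sigma)
      g2 <- rnorm(length(signal), sd = render$rician_sigma)
      sqrt((signal + g1)^2 + g2^2)
    })
    dim(signal) <- dim(f)
  }
  image_volume(signal, sp, truth$origin,
               intensity_range = c(0, max(signal)))
}

#' Generate one paired phantom specimen
#'
#' Runs the full generator: ground-truth microstructure, microCT-like and
#' MR-like renderings. Noise seeds for the two renderings are derived
#' deterministically from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param microct a [microct_render_spec()].
#' @param mr an [mr_render_spec()].
#' @return A `phantom_bundle` list with elements `truth`, `microct_volume`,
#'   `mr_volume`, `true_bvtv`, `plate_rows`, and `spec`.
#' @export
generate_phantom <- function(spec, microct = microct_render_spec(),
                             mr = mr_render_spec()) {
  truth <- generate_microstructure(spec)
  ct <- render_microct(truth, microct, seed = sub_seed(spec$seed, 1))
  mrv <- render_mr(truth, mr, seed = sub_seed(spec$seed, 2))
  structure(
    list(truth = truth, microct_volume = ct, mr_volume = mrv,
         true_bvtv = attr(truth, "true_bvtv"),
         plate_rows = attr(truth, "plate_rows"),
         margin_rows = attr(truth, "margin_rows"), spec = spec),
    class = "phantom_bundle"
  )
}

sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Generate a synthetic cohort of paired phantoms
#'
#' Stands in for a set of cadaveric specimens: `n` phantom bundles with true
#' BV/TV evenly spread over `bvtv_range` and side labels alternating
#' right/left (purely to exercise the subgroup analysis; no anatomical
#' asymmetry is modelled).
#'
#' @param n number of specimens (>= 2).
#' @param bvtv_range length-2 numeric, range of true BV/TV fractions.
#' @param spec_template a [phantom_spec()] whose geometry fields are reused
#'   for every specimen (its `target_bvtv` and `seed` are overridden).
#' @param microct,mr render specifications shared by all specimens.
#' @param seed cohort-level seed; per-specimen seeds are derived from it.
#' @return A list with `bundles` (list of `phantom_bundle`) and `truth`
#'   (tibble: `id`, `side`, `true_bvtv_percent`).
#' @export
generate_cohort <- function(n, bvtv_range = c(0.10, 0.45),
                            spec_template = phantom_spec(0.3),
                            microct = microct_render_spec(),
                            mr = mr_render_spec(),
                            seed = 1L) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (length(bvtv_range) != 2 || any(!is.finite(bvtv_range)) ||
      bvtv_range[2] < bvtv_range[1]) {
    stop("bvtv_range must be a non-empty numeric interval", call. = FALSE)
  }
  targets <- seq(bvtv_range[1], bvtv_range[2], length.out = n)
  bundles <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec_template
    sp$target_bvtv <- targets[i]
    sp$seed <- sub_seed(seed, i)
    bundles[[i]] <- generate_phantom(sp, microct = microct, mr = mr)
  }
  truth <- tibble::tibble(
    id = sprintf("S%02d", seq_len(n)),
    side = rep(c("right", "left"), length.out = n),
    true_bvtv_percent = 100 * vapply(bundles, `[[`, numeric(1), "true_bvtv")
  )
  list(bundles = bundles, truth = truth)
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle> true BV/TV ", signif(100 * x$true_bvtv, 4),
      "% | truth ", paste(dim(x$truth$mask), collapse = "x"),
      " @ ", x$truth$spacing[1], " mm | MR ",
      paste(dim(x$mr_volume$voxels), collapse = "x"), "\n", sep = "")
  invisible(x)
}
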