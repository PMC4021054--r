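#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving the simulate /
#' measure / validate pipeline. Any subset of fields can be overridden; the
#' rest keep their defaults. The defaults describe the synthetic study: a
#' ten-specimen cohort with true BV/TV spread over 0.10-0.45, default
#' phantom geometry and noise, the MR pixel-counting analysis with a
#' cortical-bone-calibrated threshold, and the microCT marching-tetrahedra
#' estimator on the sub-plate VOI.
#'
#' The MR analysis defaults (`roi_width = 9` mm, `n_slices = 8`) are sized to
#' the default 10 x 10 mm phantom footprint; for full-size acquisitions use
#' the protocol dimensions (15.00 mm, 20 slices) via overrides.
#'
#' @param ... named overrides of the default blocks (`phantom`,
#'   `microct_render`, `mr_render`, `mr_analysis`, `microct_analysis`,
#'   `stats`, `seed`). Blocks are merged field-wise.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    phantom = list(n_specimens = 10, bvtv_range = c(0.10, 0.45),
                   trabecular_scale = 0.3, voi_extent = c(4, 10, 10),
                   fine_spacing = 0.05, cortical_plate_thickness = 0.4,
                   superior_margin = 0.3),
    microct_render = list(bone_gray = 180, marrow_gray = 40, noise_sigma = 5),
    mr_render = list(bone_signal = 20, marrow_signal = 200,
                     mr_spacing = c(0.25, 0.25, 1), rician_sigma = 10),
    mr_analysis = list(roi_anchor = c(0, 0), roi_height = 3.75,
                       roi_width = 9, n_slices = 8,
                       threshold_statistic = "mean", threshold = NULL),
    microct_analysis = list(lower = 80, upper = 255,
                            estimator = "marching_cubes",
                            include_plate = FALSE),
    stats = list(ci_level = 0.95, ci_method = "fisher"),
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown config block(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg <- defaults
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(defaults[[nm]])) {
      ov <- as.list(overrides[[nm]])
      unknown <- setdiff(names(ov), names(defaults[[nm]]))
      if (length(unknown)) {
        stop("unknown field(s) in config block '", nm, "': ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      modifyList(defaults[[nm]], ov)
    } else {
      overrides[[nm]]
    }
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  # re-check the owning modules' invariants at load time
  with(cfg$phantom, {
    if (n_specimens < 0) stop("phantom n_specimens must be >= 0", call. = FALSE)
    phantom_spec(mean(bvtv_range), trabecular_scale, voi_extent,
                 fine_spacing, cortical_plate_thickness, superior_margin)
  })
  do.call(microct_render_spec, cfg$microct_render)
  do.call(mr_render_spec, cfg$mr_render)
  with(cfg$mr_analysis, {
    if (roi_height <= 0 || roi_width <= 0 || n_slices < 1) {
      stop("invalid MR analysis geometry", call. = FALSE)
    }
  })
  with(cfg$microct_analysis, {
    if (lower > upper) stop("microCT lower threshold exceeds upper",
                            call. = FALSE)
    if (!estimator %in% c("marching_cubes", "voxel_count")) {
      stop("unknown microCT estimator: ", estimator, call. = FALSE)
    }
  })
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()] blocks.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_phantom_spec <- function(cfg, target_bvtv, seed) {
  phantom_spec(target_bvtv,
               trabecular_scale = cfg$phantom$trabecular_scale,
               voi_extent = cfg$phantom$voi_extent,
               fine_spacing = cfg$phantom$fine_spacing,
               cortical_plate_thickness = cfg$phantom$cortical_plate_thickness,
               superior_margin = cfg$phantom$superior_margin,
               seed = seed)
}

config_render_specs <- function(cfg) {
  list(microct = do.call(microct_render_spec, cfg$microct_render),
       mr = do.call(mr_render_spec, cfg$mr_render))
}

#' Generate the configured synthetic cohort
#'
#' @param config a [pipeline_config()].
#' @param seed overrides `config$seed` when given.
#' @return As [generate_cohort()]: list with `bundles` and `truth`.
#' @export
simulate_cohort <- function(config = pipeline_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  rs <- config_render_specs(config)
  generate_cohort(config$phantom$n_specimens, config$phantom$bvtv_range,
                  spec_template = config_phantom_spec(config, 0.3, 1L),
                  microct = rs$microct, mr = rs$mr, seed = seed)
}

#' Measure both modalities of one phantom bundle
#'
#' MR: standardized central ROI stack and pixel counting at the supplied
#' cortical threshold. MicroCT: global binarization and the configured BV/TV
#' estimator over the trabecular VOI (placed below the cortical plate unless
#' `include_plate`).
#'
#' @param bundle a `phantom_bundle`.
#' @param config a [pipeline_config()].
#' @param threshold scalar MR intensity threshold or `threshold_calibration`.
#' @return One-row tibble: `true_bvtv_percent`, `microct_bvtv_percent`,
#'   `mr_bvtv_percent`.
#' @export
measure_bundle <- function(bundle, config = pipeline_config(), threshold) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  row <- measure_volumes(bundle$mr_volume, bundle$microct_volume, config,
                         threshold)
  dplyr::bind_cols(tibble::tibble(true_bvtv_percent = 100 * bundle$true_bvtv),
                   row)
}

# Measurement core shared by in-memory bundles and on-disk volumes.
measure_volumes <- function(mr_volume, microct_volume, config, threshold) {
  ma <- config$mr_analysis
  rois <- central_roi_stack(mr_volume, anchor = ma$roi_anchor,
                            height_mm = ma$roi_height,
                            width_mm = ma$roi_width, n_slices = ma$n_slices)
  mr_res <- apparent_bvtv(mr_volume, rois, threshold)

  ca <- config$microct_analysis
  mask <- binarize_global(microct_volume, ca$lower, ca$upper)
  top_mm <- config$phantom$cortical_plate_thickness +
    config$phantom$superior_margin
  ext <- volume_extent(mask)
  voi <- if (isTRUE(ca$include_plate)) {
    voi_spec(ext, placement = c(0, 0, 0))
  } else {
    voi_spec(ext - c(top_mm, 0, 0), placement = c(top_mm, 0, 0))
  }
  sub <- extract_voi(mask, voi)
  ct_res <- if (ca$estimator == "marching_cubes") marching_cubes_bvtv(sub)
            else voxel_count_bvtv(sub)

  tibble::tibble(microct_bvtv_percent = ct_res$bvtv_percent,
                 mr_bvtv_percent = mr_res$mean_bvtv_percent)
}

#' Measure a whole cohort
#'
#' Calibrates one standardized cortical threshold for the cohort (from a
#' synthetic cortical-bone rendering sharing the MR settings, unless a
#' threshold is fixed in the config) and measures every bundle.
#'
#' @param cohort output of [simulate_cohort()] / [generate_cohort()].
#' @param config a [pipeline_config()].
#' @param seed seed for the calibration rendering; defaults to `config$seed`.
#' @return Tibble with one row per specimen: `id`, `side`,
#'   `true_bvtv_percent`, `microct_bvtv_percent`, `mr_bvtv_percent`, plus the
#'   `threshold` used as an attribute.
#' @export
measure_cohort <- function(cohort, config = pipeline_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  threshold <- cohort_threshold(config, seed)
  rows <- purrr::imap(cohort$bundles, function(b, i) {
    dplyr::bind_cols(cohort$truth[i, c("id", "side")],
                     measure_bundle(b, config, threshold)[,
                       c("microct_bvtv_percent", "mr_bvtv_percent")])
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(cohort$truth, out, by = c("id", "side"))
  attr(out, "threshold") <- threshold
  out
}

cohort_threshold <- function(config, seed) {
  if (!is.null(config$mr_analysis$threshold)) {
    return(config$mr_analysis$threshold)
  }
  rs <- config_render_specs(config)
  cal <- synthetic_cortical_calibration(
    rs$mr, seed = sub_seed(seed, 99),
    statistic = config$mr_analysis$threshold_statistic)
  cal$threshold
}

#' Simulate a cohort and write it to disk
#'
#' Writes, per specimen, the ground-truth mask and both rendered volumes as
#' NIfTI (microCT additionally as an 8-bit multi-page TIFF stack when
#' `microct_tiff`), a `truth.csv` table, and a run manifest with the seed and
#' file digests.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param seed overrides `config$seed`.
#' @param microct_tiff also write the microCT volumes as TIFF stacks.
#' @return File path of the truth table, invisibly.
#' @export
run_simulate <- function(out_dir, config = pipeline_config(), seed = NULL,
                         microct_tiff = FALSE) {
  if (is.null(seed)) seed <- config$seed
  if (config$phantom$n_specimens < 2) {
    stop("config phantom n_specimens must be >= 2; nothing written", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config, seed)
  files <- character(0)
  for (i in seq_along(cohort$bundles)) {
    b <- cohort$bundles[[i]]
    id <- cohort$truth$id[i]
    f_truth <- file.path(out_dir, paste0(id, "_truth.nii.gz"))
    f_mr <- file.path(out_dir, paste0(id, "_mr.nii.gz"))
    f_ct <- file.path(out_dir, paste0(id, "_microct.nii.gz"))
    write_volume_nifti(b$truth, f_truth)
    write_volume_nifti(b$mr_volume, f_mr)
    write_volume_nifti(b$microct_volume, f_ct)
    files <- c(files, f_truth, f_mr, f_ct)
    if (microct_tiff) {
      f_tif <- file.path(out_dir, paste0(id, "_microct.tif"))
      write_volume_tiff(b$microct_volume, f_tif)
      files <- c(files, f_tif)
    }
  }
  truth_path <- file.path(out_dir, "truth.csv")
  readr::write_csv(cohort$truth, truth_path)
  write_manifest(out_dir, config, seed, c(files, truth_path))
  invisible(truth_path)
}

#' Measure an on-disk cohort
#'
#' Reads the `truth.csv` and the per-specimen MR / microCT NIfTI volumes
#' written by [run_simulate()], measures both modalities, and writes
#' `measurements.csv`.
#'
#' @param in_dir directory produced by [run_simulate()].
#' @param config a [pipeline_config()] (must match the simulated geometry).
#' @param seed seed for threshold calibration; defaults to `config$seed`.
#' @return The measurements tibble, invisibly.
#' @export
run_measure <- function(in_dir, config = pipeline_config(), seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  truth_path <- file.path(in_dir, "truth.csv")
  if (!file.exists(truth_path)) {
    stop("missing truth.csv in ", in_dir, call. = FALSE)
  }
  truth <- readr::read_csv(truth_path, show_col_types = FALSE)
  threshold <- cohort_threshold(config, seed)
  rows <- purrr::map(seq_len(nrow(truth)), function(i) {
    id <- truth$id[i]
    mr <- read_volume_nifti(file.path(in_dir, paste0(id, "_mr.nii.gz")))
    ct <- read_volume_nifti(file.path(in_dir, paste0(id, "_microct.nii.gz")))
    tryCatch(
      measure_volumes(mr, ct, config, threshold),
      error = function(e) stop("measurement failed for specimen ", id, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  out <- dplyr::bind_cols(truth, dplyr::bind_rows(rows))
  out_path <- file.path(in_dir, "measurements.csv")
  readr::write_csv(out, out_path)
  write_manifest(in_dir, config, seed, out_path,
                 name = "measure_manifest.json")
  invisible(out)
}

#' Validate paired measurements
#'
#' Runs the full agreement analysis on a measurements table (or CSV path)
#' and, when `out_dir` is given, writes the report as JSON together with the
#' Bland-Altman scatter data as CSV.
#'
#' @param measurements data frame or CSV path with columns
#'   `microct_bvtv_percent`, `mr_bvtv_percent` and optionally `side`.
#' @param config a [pipeline_config()] (its `stats` block is used).
#' @param out_dir optional output directory.
#' @return The `bvtv_agreement` report.
#' @export
run_validate <- function(measurements, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(measurements)) {
    measurements <- readr::read_csv(measurements, show_col_types = FALSE)
  }
  report <- agreement_report(measurements,
                             ci_level = config$stats$ci_level,
                             ci_method = config$stats$ci_method)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(agreement_json(report),
                         file.path(out_dir, "agreement_report.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(tidy(report$bland_altman),
                     file.path(out_dir, "bland_altman.csv"))
  }
  report
}

agreement_json <- function(report) {
  list(n = report$n, spearman_rho = report$spearman_rho,
       ci_level = report$ci_level, ci_method = report$ci_method,
       ci_low = report$ci_low, ci_high = report$ci_high,
       by_side = report$by_side,
       bland_altman = glance(report$bland_altman))
}

#' Reproduce the cadaveric validation analysis
#'
#' Runs the agreement analysis on the bundled ten-knee cadaveric dataset and
#' prints the pooled correlation with its confidence interval, the per-side
#' correlations, and the Bland-Altman bias. The pooled correlation (2
#' decimals, half-up) is checked against the expected constant stored
#' alongside the data.
#'
#' @param json return the report as a JSON string instead of printing.
#' @param quiet suppress printing.
#' @return Invisibly, a list with the `bvtv_agreement` `report` and `ok`
#'   (logical: pooled correlation matches the stored constant).
#' @export
reproduce_cadaver <- function(json = FALSE, quiet = FALSE) {
  data <- load_cadaver_bvtv()
  meta <- cadaver_bvtv_meta()
  report <- agreement_report(data)
  ok <- isTRUE(all.equal(round_half_up(report$spearman_rho, 2),
                         meta$expected$spearman_rho_2dp))
  if (json) {
    out <- jsonlite::toJSON(agreement_json(report), auto_unbox = TRUE,
                            digits = NA)
    if (!quiet) cat(out, "\n")
  } else if (!quiet) {
    print(report)
    if (!ok) {
      cat("WARNING: pooled correlation does not match the stored constant ",
          meta$expected$spearman_rho_2dp, "\n", sep = "")
    }
  }
  invisible(list(report = report, ok = ok))
}

write_manifest <- function(out_dir, config, seed, files,
                           name = "manifest.json") {
  manifest <- list(
    package = "bvtvtools",
    version = as.character(utils::packageVersion("bvtvtools")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = unclass(config),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, name),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
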