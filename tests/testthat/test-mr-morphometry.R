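make_volume <- function(vals, spacing = c(0.25, 0.25, 1)) {
  image_volume(vals, spacing)
}

test_that("ROI pixel membership follows the center-in-rectangle rule", {
  v <- make_volume(array(0, c(16, 16, 2)))
  # brute-force center enumeration oracle
  count_oracle <- function(from, len, s, n) {
    centers <- (seq_len(n) - 0.5) * s
    sum(centers >= from & centers < from + len)
  }
  m <- roi_to_voxels(v, physical_roi(1, c(0, 0), 1, 1))
  expect_equal(m$n_pixels, count_oracle(0, 1, 0.25, 16)^2)  # 4 x 4 = 16

  one <- roi_to_voxels(v, physical_roi(1, c(0, 0), 0.25, 0.25))
  expect_equal(one$n_pixels, 1)

  v23 <- make_volume(array(0, c(16, 16, 2)), c(0.23, 0.23, 1))
  cal <- roi_to_voxels(v23, physical_roi(2, c(0, 0), 0.69, 0.69))
  expect_equal(length(cal$rows), count_oracle(0, 0.69, 0.23, 16))  # 3
  expect_equal(cal$n_pixels, 9)
  # an offset anchor keeps the count (translation invariance of the grid rule)
  cal2 <- roi_to_voxels(v23, physical_roi(2, c(0.69, 1.38), 0.69, 0.69))
  expect_equal(cal2$n_pixels, 9)

  expect_error(roi_to_voxels(v, physical_roi(1, c(3.8, 0), 1, 1)), "vertical")
  expect_error(roi_to_voxels(v, physical_roi(1, c(0, 3.8), 1, 1)),
               "medial-lateral")
  expect_error(roi_to_voxels(v, physical_roi(3, c(0, 0), 1, 1)),
               "anterior-posterior")
  expect_error(physical_roi(1, c(0, 0), 0, 1), "> 0")
})

test_that("the central ROI stack is centered with a lower-index tie-break", {
  mk <- function(n) make_volume(array(0, c(8, 8, n)))
  idx <- function(rois) vapply(rois, `[[`, integer(1), "slice_index")
  expect_equal(idx(central_roi_stack(mk(72), c(0, 0), 1, 1, 20)), 27:46)
  expect_equal(idx(central_roi_stack(mk(21), c(0, 0), 1, 1, 20)), 1:20)
  expect_equal(idx(central_roi_stack(mk(20), c(0, 0), 1, 1, 20)), 1:20)
  expect_error(central_roi_stack(mk(10), c(0, 0), 1, 1, 20), "10 slices")
})

test_that("cortical threshold calibration pools pixels across the 20 ROIs", {
  v <- make_volume(array(10, c(40, 40, 2)), c(0.23, 0.23, 1))
  rois <- calibration_roi_grid(v, n = 20, top_left = c(0.1, 0.1),
                               slice_indices = 1:2)
  cal <- calibrate_cortical_threshold(v, rois)
  expect_equal(cal$threshold, 10)
  expect_equal(nrow(cal$per_roi), 20)

  # two intensity groups with equal pixel counts average to the midpoint
  vals <- array(8, c(40, 40, 2)); vals[, , 2] <- 12
  v2 <- make_volume(vals, c(0.23, 0.23, 1))
  rois2 <- c(calibration_roi_grid(v2, 10, c(0.1, 0.1), 1L),
             calibration_roi_grid(v2, 10, c(0.1, 0.1), 2L))
  cal2 <- calibrate_cortical_threshold(v2, rois2)
  expect_equal(cal2$threshold, 10)
  expect_gte(cal2$threshold, cal2$pixel_range[1])
  expect_lte(cal2$threshold, cal2$pixel_range[2])

  expect_error(calibrate_cortical_threshold(v, rois[1:19]), "exactly 20")
  big <- replicate(20, physical_roi(1, c(0, 0), 2, 2), simplify = FALSE)
  expect_error(calibrate_cortical_threshold(v, big), "0.69")

  # alternative statistics move the threshold as documented
  noisy <- make_volume(array(rnorm(40 * 40 * 2, 10), c(40, 40, 2)),
                       c(0.23, 0.23, 1))
  m0 <- calibrate_cortical_threshold(noisy, rois)$threshold
  m1 <- calibrate_cortical_threshold(noisy, rois, statistic = "mean_sd",
                                     k_sd = 1)$threshold
  expect_gt(m1, m0)
})

test_that("calibration on Rician cortical renderings stays in the known band", {
  # Rice(20, 10) has mean ~23.7; the pooled-mean threshold stays well inside
  # [15, 35] across seeds
  thresholds <- vapply(1:50, function(s) {
    synthetic_cortical_calibration(seed = s)$threshold
  }, numeric(1))
  expect_true(all(thresholds > 15 & thresholds < 35))
})

test_that("apparent BV/TV counts pixels at or below the threshold", {
  vals <- array(100, c(4, 4, 2))
  vals[1, 1:3, 1] <- 10  # 3 of 16 pixels at/below in slice 1
  v <- make_volume(vals, c(0.25, 0.25, 1))
  roi <- function(sl) physical_roi(sl, c(0, 0), 1, 1)

  res <- apparent_bvtv(v, list(roi(1)), threshold = 10)
  expect_equal(res$mean_bvtv, 3 / 16)  # inclusive comparison

  expect_equal(apparent_bvtv(v, list(roi(1)), 500)$mean_bvtv, 1)
  expect_equal(apparent_bvtv(v, list(roi(1)), 5)$mean_bvtv, 0)

  # per-slice fractions are averaged
  vals2 <- array(100, c(10, 10, 2))
  vals2[1:2, , 1] <- 0   # slice 1: 0.2
  vals2[1:4, , 2] <- 0   # slice 2: 0.4
  v2 <- make_volume(vals2, c(0.1, 0.1, 1))
  res2 <- apparent_bvtv(v2, list(roi(1), roi(2)), threshold = 50)
  expect_equal(res2$per_slice$bvtv, c(0.2, 0.4))
  expect_equal(res2$mean_bvtv, 0.3)
  expect_equal(res2$mean_bvtv_percent, 30)
  expect_equal(glance(res2)$mean_bvtv, 0.3)
  expect_equal(nrow(tidy(res2)), 2)
})

test_that("apparent BV/TV is monotone in the threshold", {
  v <- make_volume(withr::with_seed(1, array(rnorm(8 * 8 * 4, 100, 30),
                                             c(8, 8, 4))))
  rois <- central_roi_stack(v, c(0, 0), 1.5, 1.5, 4)
  fracs <- vapply(seq(20, 180, by = 10), function(th) {
    apparent_bvtv(v, rois, th)$mean_bvtv
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("apparent BV/TV is invariant under monotone intensity transforms", {
  v <- make_volume(withr::with_seed(2, array(rnorm(8 * 8 * 4, 100, 30),
                                             c(8, 8, 4))))
  rois <- central_roi_stack(v, c(0, 0), 1.5, 1.5, 4)
  th <- 95
  base <- apparent_bvtv(v, rois, th)$per_slice$bvtv
  for (fun in list(function(x) 3 * x + 7, function(x) exp(x / 50),
                   function(x) x^3)) {
    tv <- image_volume(fun(v$voxels), v$spacing)
    expect_equal(apparent_bvtv(tv, rois, fun(th))$per_slice$bvtv, base)
  }
})

test_that("noiseless fine-resolution MR recovers the exact bone fraction", {
  sp <- small_spec(0.3, seed = 13)
  truth <- generate_microstructure(sp)
  mr <- render_mr(truth, mr_render_spec(mr_spacing = truth$spacing,
                                        rician_sigma = 0))
  top <- (attr(truth, "margin_rows") + attr(truth, "plate_rows")) *
    truth$spacing[1]
  n_sl <- dim(mr$voxels)[3]
  rois <- central_roi_stack(mr, c(top, 0), height_mm = 2.4, width_mm = 2.4,
                            n_slices = n_sl)
  res <- apparent_bvtv(mr, rois, threshold = 110)
  expect_equal(res$mean_bvtv, attr(truth, "true_bvtv"), tolerance = 1e-12)
})

test_that("partial volume with a plate-calibrated threshold underestimates", {
  # noiseless: the calibration volume is constant bone_signal, so the
  # threshold equals bone_signal and only pure-bone MR voxels are counted
  cal <- synthetic_cortical_calibration(mr_render_spec(rician_sigma = 0),
                                        seed = 2)
  expect_equal(cal$threshold, 20)
  for (target in c(0.15, 0.35, 0.5)) {
    truth <- generate_microstructure(small_spec(target, seed = 17))
    mr <- render_mr(truth, mr_render_spec(rician_sigma = 0))
    rois <- central_roi_stack(mr, c(0, 0), height_mm = 2, width_mm = 2,
                              n_slices = 2)
    res <- apparent_bvtv(mr, rois, cal)
    expect_lte(res$mean_bvtv, attr(truth, "true_bvtv"))
  }
})
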