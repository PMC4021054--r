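test_that("Spearman correlation matches the rank definition", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(spearman_rho(x, x^3 + 2), 1)        # monotone transform
  expect_equal(spearman_rho(x, -x), -1)            # reversed ordering
  # no ties: 1 - 6 sum(d^2) / (n (n^2 - 1)) longhand
  y <- c(3, 1, 7, 2, 9)
  d <- rank(x) - rank(y)
  expect_equal(spearman_rho(x, y), 1 - 6 * sum(d^2) / (5 * 24))
  # ties: mid-rank Pearson oracle
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 2, 4, 4, 4, 7, 8, 8)
  expect_equal(spearman_rho(xt, yt),
               pearson_oracle(midrank(xt), midrank(yt)))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:5, rep(2, 5)), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(31, {
    for (i in 1:10) {
      x <- rnorm(12); y <- x + rnorm(12)
      rho <- spearman_rho(x, y)
      expect_equal(spearman_rho(exp(x), y), rho)
      expect_equal(spearman_rho(x, atan(y)), rho)
      expect_equal(spearman_rho(2 * x + 1, y^3), rho)
    }
  })
})

test_that("Fisher-z interval matches its closed form and nests properly", {
  ci <- spearman_ci_fisher(0.9, 5)
  half <- qnorm(0.975) / sqrt(2)
  expect_equal(unname(ci), tanh(atanh(0.9) + c(-half, half)))

  # centered and shrinking for rho = 0
  ci100 <- spearman_ci_fisher(0, 100)
  expect_equal(unname(ci100[1]), -unname(ci100[2]))
  expect_lt(diff(spearman_ci_fisher(0, 400)), diff(ci100) * 0.55)

  # 99% interval contains the 95% interval
  for (rho in c(-0.5, 0, 0.7)) {
    c95 <- spearman_ci_fisher(rho, 12, 0.95)
    c99 <- spearman_ci_fisher(rho, 12, 0.99)
    expect_lt(c99[1], c95[1])
    expect_gt(c99[2], c95[2])
  }

  # Bonett-Wright variant widens the interval for nonzero rho
  cb <- spearman_ci_fisher(0.8, 10, method = "bonett")
  cf <- spearman_ci_fisher(0.8, 10)
  expect_lt(cb[1], cf[1])
  expect_error(spearman_ci_fisher(1, 10), "degenerate")
})

test_that("the Fisher-z design size reproduces the ten-knee computation", {
  expect_identical(sample_size_for_correlation(0.80), 10L)
  # closed-form oracle at a different alternative
  oracle <- ceiling(((qnorm(0.975) + qnorm(0.8)) / atanh(0.5))^2 + 3)
  expect_identical(sample_size_for_correlation(0.5), as.integer(oracle))
  # atanh diverges as rho -> 1, leaving the +3 floor
  expect_identical(sample_size_for_correlation(0.999999), 4L)
  expect_error(sample_size_for_correlation(0), "exceed")
})

test_that("per-side correlations respect the side labels", {
  d <- tibble::tibble(
    side = rep(c("right", "left"), each = 4),
    microct_bvtv_percent = c(1, 2, 3, 4, 1, 2, 3, 4),
    mr_bvtv_percent = c(2, 3, 4, 5, 8, 6, 4, 2)
  )
  out <- subgroup_correlations(d)
  expect_equal(out$rho[out$side == "right"], 1)
  expect_equal(out$rho[out$side == "left"], -1)

  same <- dplyr::mutate(d, mr_bvtv_percent = microct_bvtv_percent + 1)
  expect_equal(unique(subgroup_correlations(same)$rho), 1)

  short <- d[c(1, 2, 5:8), ]
  expect_warning(out2 <- subgroup_correlations(short), "skipped")
  expect_true(is.na(out2$rho[out2$side == "right"]))
})

test_that("Bland-Altman reports bias and 1.96-sd limits of agreement", {
  x <- c(10, 20, 30)
  expect_equal(glance(bland_altman(x, x)),
               tibble::tibble(bias = 0, sd_diff = 0, loa_low = 0,
                              loa_high = 0, n = 3L))
  ba <- bland_altman(x, x + 5)
  expect_equal(ba$bias, 5)
  expect_equal(ba$sd_diff, 0)

  withr::with_seed(41, {
    xx <- runif(40, 10, 50); yy <- xx + rnorm(40, -3, 2)
  })
  ba2 <- bland_altman(xx, yy)
  expect_equal(ba2$bias, mean(yy - xx))
  expect_equal(ba2$loa_low, ba2$bias - 1.96 * sd(yy - xx))
  expect_equal(ba2$loa_high, ba2$bias + 1.96 * sd(yy - xx))
  expect_equal(nrow(tidy(ba2)), 40)
  expect_error(bland_altman(1, numeric(0)), "equal length")
})

test_that("Bland-Altman limits cover about 95% of Gaussian differences", {
  withr::with_seed(42, {
    x <- runif(2000, 10, 50)
    y <- x + rnorm(2000, -5, 3)
  })
  ba <- bland_altman(x, y)
  inside <- mean(ba$pairs$diff >= ba$loa_low & ba$pairs$diff <= ba$loa_high)
  expect_gt(inside, 0.93)  # binomial band around 0.95 at n = 2000
  expect_lt(inside, 0.97)
})

test_that("ICC(3,1) matches the from-scratch ANOVA oracle", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2)
  expect_equal(icc_3_1(cbind(m[, 1], m[, 1])), 1)      # identical raters
  expect_equal(icc_3_1(cbind(m[, 1], m[, 1] + 10)), 1)  # fixed offset
  withr::with_seed(51, {
    for (i in 1:5) {
      r <- matrix(rnorm(12), nrow = 6)
      expect_equal(icc_3_1(r), icc_oracle(r))
    }
    wide <- matrix(rnorm(40), nrow = 10)  # k = 4 raters
    expect_equal(icc_3_1(wide), icc_oracle(wide))
  })
  expect_error(icc_3_1(matrix(c(1, NA, 2, 3), 2)), "complete")
  expect_error(icc_3_1(matrix(1:3, ncol = 1)), ">= 2")
})

test_that("ICC(3,1) recovers a known population consistency ICC", {
  # targets b ~ N(0, 2^2), residual e ~ N(0, 1): ICC = 4 / 5
  withr::with_seed(52, {
    b <- rnorm(200, 0, 2)
    m <- cbind(b + rnorm(200), b + rnorm(200) + 3)  # rater offset is ignored
  })
  expect_equal(icc_3_1(m), 0.8, tolerance = 0.06)
})

test_that("RMS %CV follows the duplicate-measurement definition", {
  expect_equal(rms_percent_cv(cbind(c(5, 7), c(5, 7))), 0)
  # single pair (1, 3): sd = sqrt(2), mean = 2, cv = 0.7071
  expect_equal(rms_percent_cv(matrix(c(1, 3), nrow = 1)), 100 / sqrt(2),
               tolerance = 1e-10)
  withr::with_seed(61, {
    p <- cbind(runif(10, 5, 20), runif(10, 5, 20))
  })
  expect_equal(rms_percent_cv(3.7 * p), rms_percent_cv(p))  # scale invariant
  # n-divisor variant is smaller by sqrt(2)
  expect_equal(rms_percent_cv(p, divisor = "n"),
               rms_percent_cv(p) / sqrt(2))
  expect_error(rms_percent_cv(cbind(1, -1)), "non-positive")
})

test_that("reliability_report bundles ICC, extreme differences and RMS %CV", {
  d <- tibble::tibble(read1 = c(10, 20, 30, 40), read2 = c(11, 19, 33, 40))
  out <- reliability_report(d)
  expect_equal(out$n, 4L)
  expect_equal(out$icc_3_1, icc_oracle(cbind(d$read1, d$read2)))
  expect_equal(out$min_diff, -1)
  expect_equal(out$max_diff, 3)
  expect_equal(out$rms_percent_cv, rms_percent_cv(cbind(d$read1, d$read2)))
})

test_that("agreement_report combines correlation, CI, sides and bias", {
  data <- load_cadaver_bvtv()
  rep <- agreement_report(data)
  expect_s3_class(rep, "bvtv_agreement")
  expect_equal(rep$n, 10)
  expect_equal(rep$spearman_rho,
               cor(rank(data$microct_bvtv_percent),
                   rank(data$mr_bvtv_percent)))
  g <- glance(rep)
  expect_equal(g$bias, mean(data$mr_bvtv_percent - data$microct_bvtv_percent))
  td <- tidy(rep)
  expect_true(all(c("spearman_rho", "bland_altman_bias",
                    "spearman_rho_left", "spearman_rho_right") %in% td$term))
  expect_error(agreement_report(data[1:2, ]), "insufficient")
  expect_error(agreement_report(data.frame(a = 1:5)), "must contain")

  p1 <- autoplot(rep)
  p2 <- autoplot(rep, type = "scatter")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})

test_that("half-up rounding differs from banker's rounding where it should", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(-0.005, 2), -0.01)
  expect_equal(round_half_up(0.825, 2), 0.83)
  expect_equal(round_half_up(2.4, 0), 2)
})
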