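#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); with no ties it
#' equals `1 - 6 * sum(d^2) / (n (n^2 - 1))`.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no missing values.
#' @return The correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  check_paired(x, y, min_n = 3)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  }
  cor(x, y, method = "spearman")
}

check_paired <- function(x, y, min_n = 2) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (length(x) < min_n) {
    stop("need at least ", min_n, " pairs, got ", length(x), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fisher-z confidence interval for a correlation
#'
#' Transforms `rho` with `atanh`, builds a normal interval with standard error
#' `1 / sqrt(n - 3)` (or the Bonett-Wright variant
#' `sqrt((1 + rho^2 / 2) / (n - 3))`), and back-transforms with `tanh`.
#'
#' @param rho correlation coefficient, `|rho| < 1`.
#' @param n sample size (>= 4).
#' @param level confidence level (default 0.95).
#' @param method `"fisher"` (default) or `"bonett"`.
#' @return Named numeric `c(ci_low, ci_high)`.
#' @export
spearman_ci_fisher <- function(rho, n, level = 0.95,
                               method = c("fisher", "bonett")) {
  method <- match.arg(method)
  stopifnot(n >= 4, level > 0, level < 1)
  if (abs(rho) >= 1) {
    stop("|rho| = 1: Fisher-z interval degenerate", call. = FALSE)
  }
  se <- switch(method,
               fisher = 1 / sqrt(n - 3),
               bonett = sqrt((1 + rho^2 / 2) / (n - 3)))
  z <- atanh(rho)
  half <- qnorm((1 + level) / 2) * se
  c(ci_low = tanh(z - half), ci_high = tanh(z + half))
}

#' Fisher-z sample size for detecting a correlation
#'
#' Minimum number of independent pairs for a two-sided test of
#' `rho = rho_null` against `rho = rho_alt` at significance `alpha` and the
#' requested power, using the Fisher-z approximation:
#' `n = ceiling(((z_{1-alpha/2} + z_{power}) / (atanh(rho_alt) -
#' atanh(rho_null)))^2 + 3)`.
#'
#' @param rho_alt correlation under the alternative, `0 < rho_alt < 1`.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param rho_null correlation under the null (default 0).
#' @return Integer sample size.
#' @examples
#' sample_size_for_correlation(0.80)  # 10
#' @export
sample_size_for_correlation <- function(rho_alt, alpha = 0.05, power = 0.80,
                                        rho_null = 0) {
  if (rho_alt <= rho_null) stop("rho_alt must exceed rho_null", call. = FALSE)
  stopifnot(rho_alt < 1, rho_alt > 0)
  num <- qnorm(1 - alpha / 2) + qnorm(power)
  den <- atanh(rho_alt) - atanh(rho_null)
  as.integer(ceiling((num / den)^2 + 3))
}

#' Per-side Spearman correlations
#'
#' Computes [spearman_rho()] between the microCT and MR BV/TV columns within
#' each side label. Sides with fewer than 3 pairs are skipped with a warning.
#'
#' @param data data frame with columns `side`, `microct_bvtv_percent`,
#'   `mr_bvtv_percent`.
#' @return Tibble with columns `side`, `n`, `rho`.
#' @export
subgroup_correlations <- function(data) {
  stopifnot(all(c("side", "microct_bvtv_percent", "mr_bvtv_percent") %in%
                  names(data)))
  data |>
    dplyr::group_by(.data$side) |>
    dplyr::summarise(
      n = dplyr::n(),
      rho = if (dplyr::n() >= 3) {
        spearman_rho(.data$microct_bvtv_percent, .data$mr_bvtv_percent)
      } else {
        warning("side with < 3 pairs skipped", call. = FALSE)
        NA_real_
      },
      .groups = "drop"
    )
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences are `y - x`; in this package's cross-modality use the
#' convention is MR minus microCT, so systematic MR underestimation appears
#' as a negative bias. The bias is the mean difference, `sd_diff` uses the
#' `n - 1` divisor, and the 95% limits of agreement are
#' `bias +/- 1.96 * sd_diff`.
#'
#' @param x reference measurements (microCT BV/TV).
#' @param y test measurements (MR BV/TV).
#' @return A `bland_altman` object; [tidy()] returns the per-pair means and
#'   differences, [glance()] the bias and limits.
#' @export
bland_altman <- function(x, y) {
  check_paired(x, y, min_n = 2)
  d <- y - x
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
         n = length(d),
         pairs = tibble::tibble(mean = (x + y) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman> bias ", signif(x$bias, 5), " (limits ",
      signif(x$loa_low, 5), " to ", signif(x$loa_high, 5), ", n = ",
      x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, n = x$n)
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measurement, consistency ICC:
#' `(BMS - EMS) / (BMS + (k - 1) EMS)` where BMS and EMS are the between-target
#' and residual mean squares of the two-way ANOVA decomposition. Consistency
#' ICC ignores fixed rater offsets.
#'
#' @param ratings numeric matrix (or data frame) of n targets x k raters,
#'   complete, n >= 2 and k >= 2.
#' @return The ICC estimate.
#' @export
icc_3_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete", call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 targets and >= 2 raters", call. = FALSE)
  d <- data.frame(y = as.numeric(ratings),
                  target = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ target + rater, data = d))[[1]][["Mean Sq"]]
  bms <- ms[1]
  ems <- ms[3]
  (bms - ems) / (bms + (k - 1) * ems)
}

#' Root-mean-square percent coefficient of variation
#'
#' Test-retest precision error for duplicate measurements: for each pair the
#' standard deviation is `|d| / sqrt(2)` (two replicates, `n - 1` divisor; set
#' `divisor = "n"` for `|d| / 2`), the CV is sd over the pair mean, and the
#' result is `100 * sqrt(mean(cv^2))`.
#'
#' @param pairs two-column matrix or data frame of duplicate measurements
#'   (one row per specimen), all pair means strictly positive.
#' @param divisor `"n-1"` (default) or `"n"` for the per-pair sd.
#' @return RMS %CV in percent.
#' @export
rms_percent_cv <- function(pairs, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || nrow(pairs) < 1 || anyNA(pairs)) {
    stop("pairs must be a complete two-column matrix", call. = FALSE)
  }
  m <- rowMeans(pairs)
  if (any(m <= 0)) {
    stop("CV undefined: non-positive pair mean", call. = FALSE)
  }
  s <- abs(pairs[, 1] - pairs[, 2]) / switch(divisor, "n-1" = sqrt(2), "n" = 2)
  100 * sqrt(mean((s / m)^2))
}

#' Reliability report for duplicate measurements
#'
#' Summarizes test-retest reliability of duplicate reads: ICC(3,1), the
#' smallest and largest paired differences, and the RMS %CV.
#'
#' @param data data frame whose first two numeric columns (or the columns
#'   named in `cols`) hold the duplicate measurements.
#' @param cols optional length-2 character vector of column names.
#' @return A one-row tibble: `n`, `icc_3_1`, `min_diff`, `max_diff`,
#'   `rms_percent_cv`.
#' @export
reliability_report <- function(data, cols = NULL) {
  if (is.null(cols)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    if (length(num) < 2) stop("need two numeric columns", call. = FALSE)
    cols <- num[1:2]
  }
  m <- as.matrix(data[, cols])
  d <- m[, 2] - m[, 1]
  tibble::tibble(n = nrow(m), icc_3_1 = icc_3_1(m),
                 min_diff = min(d), max_diff = max(d),
                 rms_percent_cv = rms_percent_cv(m))
}

#' Cross-modality agreement report
#'
#' The pooled validation analysis for paired BV/TV measurements: Spearman
#' correlation with a Fisher-z confidence interval, per-side subgroup
#' correlations, and Bland-Altman agreement with the MR-minus-microCT
#' difference convention.
#'
#' @param data data frame with columns `microct_bvtv_percent` and
#'   `mr_bvtv_percent`, optionally `side` and `id`.
#' @param ci_level confidence level for the correlation interval.
#' @param ci_method `"fisher"` or `"bonett"`, see [spearman_ci_fisher()].
#' @return A `bvtv_agreement` object. [tidy()] returns the statistics in long
#'   form, [glance()] a one-row summary, [autoplot()] the Bland-Altman or
#'   scatter figure.
#' @examples
#' agreement_report(load_cadaver_bvtv())
#' @export
agreement_report <- function(data, ci_level = 0.95,
                             ci_method = c("fisher", "bonett")) {
  ci_method <- match.arg(ci_method)
  need <- c("microct_bvtv_percent", "mr_bvtv_percent")
  if (!all(need %in% names(data))) {
    stop("data must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) < 3) {
    stop("insufficient n: need at least 3 paired measurements",
         call. = FALSE)
  }
  x <- data$microct_bvtv_percent
  y <- data$mr_bvtv_percent
  if (any(x < 0) || any(y < 0)) {
    stop("BV/TV percentages must be >= 0", call. = FALSE)
  }
  rho <- spearman_rho(x, y)
  ci <- if (abs(rho) < 1) {
    spearman_ci_fisher(rho, length(x), ci_level, ci_method)
  } else {
    c(ci_low = rho, ci_high = rho)
  }
  by_side <- if ("side" %in% names(data)) subgroup_correlations(data)
             else NULL
  structure(
    list(n = length(x), spearman_rho = rho, ci_level = ci_level,
         ci_method = ci_method, ci_low = unname(ci[1]),
         ci_high = unname(ci[2]), by_side = by_side,
         bland_altman = bland_altman(x, y), data = tibble::as_tibble(data)),
    class = "bvtv_agreement"
  )
}

#' @export
print.bvtv_agreement <- function(x, ...) {
  cat("Cross-modality BV/TV agreement (n = ", x$n, ")\n",
      "  Spearman rho: ", round_half_up(x$spearman_rho, 2), " (",
      100 * x$ci_level, "% CI ", round_half_up(x$ci_low, 2), " to ",
      round_half_up(x$ci_high, 2), ", ", x$ci_method, ")\n", sep = "")
  if (!is.null(x$by_side)) {
    for (i in seq_len(nrow(x$by_side))) {
      cat("  ", x$by_side$side[i], " knees: rho = ",
          round_half_up(x$by_side$rho[i], 2), " (n = ", x$by_side$n[i],
          ")\n", sep = "")
    }
  }
  ba <- x$bland_altman
  cat("  Bland-Altman (MR - microCT): bias ", round_half_up(ba$bias, 2),
      ", limits ", round_half_up(ba$loa_low, 2), " to ",
      round_half_up(ba$loa_high, 2), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bvtv_agreement <- function(x, ...) {
  out <- tibble::tibble(
    term = c("spearman_rho", "bland_altman_bias", "loa_low", "loa_high"),
    estimate = c(x$spearman_rho, x$bland_altman$bias, x$bland_altman$loa_low,
                 x$bland_altman$loa_high),
    conf.low = c(x$ci_low, NA, NA, NA),
    conf.high = c(x$ci_high, NA, NA, NA)
  )
  if (!is.null(x$by_side)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("spearman_rho_", x$by_side$side),
      estimate = x$by_side$rho, conf.low = NA, conf.high = NA))
  }
  out
}

#' @export
glance.bvtv_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, spearman_rho = x$spearman_rho, ci_low = x$ci_low,
                 ci_high = x$ci_high, ci_level = x$ci_level,
                 bias = x$bland_altman$bias,
                 loa_low = x$bland_altman$loa_low,
                 loa_high = x$bland_altman$loa_high)
}

#' @param object a `bvtv_agreement` object.
#' @param type `"bland_altman"` (difference vs mean, with bias and limits) or
#'   `"scatter"` (MR vs microCT).
#' @param ... unused.
#' @rdname agreement_report
#' @export
autoplot.bvtv_agreement <- function(object, type = c("bland_altman",
                                                     "scatter"), ...) {
  type <- match.arg(type)
  if (type == "bland_altman") {
    ba <- object$bland_altman
    ggplot2::ggplot(ba$pairs, ggplot2::aes(x = mean, y = diff)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = ba$bias, colour = "red") +
      ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                          colour = "red", linetype = "dashed") +
      ggplot2::labs(x = "Mean of MR and microCT BV/TV (%)",
                    y = "MR - microCT BV/TV (%)",
                    title = "Bland-Altman agreement")
  } else {
    p <- ggplot2::ggplot(object$data,
                         ggplot2::aes(x = .data$microct_bvtv_percent,
                                      y = .data$mr_bvtv_percent))
    p <- if ("side" %in% names(object$data)) {
      p + ggplot2::geom_point(ggplot2::aes(shape = .data$side))
    } else {
      p + ggplot2::geom_point()
    }
    p + ggplot2::labs(x = "microCT BV/TV (%)", y = "MR apparent BV/TV (%)",
                      shape = "side", title = "Cross-modality BV/TV")
  }
}

#' Round half away from zero
#'
#' Rounding used when comparing computed statistics with printed values
#' (0.005 rounds to 0.01), unlike base R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
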