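# Reliability and agreement statistics: ICC(2,1) with F-based confidence
# intervals, Bland-Altman analysis with fixed/proportional bias handling.

#' Classify an ICC value
#'
#' Reliability is poor below 0.50, moderate from 0.50 to 0.75 (closed
#' interval) and good above 0.75.
#'
#' @param icc ICC value in \[-1, 1\].
#' @return `"poor"`, `"moderate"` or `"good"`.
#' @export
classify_icc <- function(icc) {
  stopifnot(is.numeric(icc), length(icc) == 1L, is.finite(icc))
  if (icc < -1 || icc > 1) stop("icc must lie in [-1, 1]", call. = FALSE)
  if (icc < 0.50) {
    "poor"
  } else if (icc <= 0.75) {
    "moderate"
  } else {
    "good"
  }
}

#' ICC(2,1): two-way random-effects, absolute-agreement, single-measure
#'
#' Computes the intraclass correlation for inter-rater reliability from the
#' two-way (subject x rater) ANOVA mean squares,
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' with the 95% confidence interval from the F-distribution method of
#' McGraw & Wong for the two-way random absolute-agreement single-measure
#' case.
#'
#' @param values Numeric matrix, subjects in rows, raters in columns; no
#'   missing cells.
#' @param alpha Significance level for the confidence interval (default
#'   0.05, i.e. a 95% CI).
#' @return Object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `n_subjects`, `n_raters`, `label` (see [classify_icc()]) and
#'   the mean squares `ms` used.
#' @examples
#' m <- cbind(c(70, 80, 90, 60), c(75, 80, 85, 70))
#' icc_2_1(m)
#' @export
icc_2_1 <- function(values, alpha = 0.05) {
  x <- as.matrix(values)
  if (!is.numeric(x) || anyNA(x)) {
    stop("values must be a complete numeric matrix", call. = FALSE)
  }
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L || k < 2L) {
    stop("need at least 3 subjects and 2 raters", call. = FALSE)
  }
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- x - outer(row_means, rep(1, k)) - outer(rep(1, n), col_means) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))

  scale_ref <- mean(x^2) + 1
  if (msr / scale_ref < 1e-14 && mse / scale_ref < 1e-14) {
    stop("degenerate variance: all values identical; ICC undefined",
      call. = FALSE
    )
  }

  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))

  if (mse / scale_ref < 1e-14) {
    # perfect agreement: no within-cell variance at all
    ci <- c(icc, icc)
  } else {
    fj <- msc / mse
    num <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    den <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- num / den
    f_u <- qf(1 - alpha / 2, n - 1, v)
    f_l <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    ci <- c(max(-1, lower), min(1, upper))
  }

  structure(
    list(
      icc = icc,
      ci_low = ci[1],
      ci_high = ci[2],
      n_subjects = n,
      n_raters = k,
      label = classify_icc(max(-1, min(1, icc))),
      ms = c(msr = msr, msc = msc, mse = mse),
      alpha = alpha
    ),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.3f, %d%% CI (%.3f, %.3f), %s agreement [n = %d subjects, k = %d raters]\n",
    x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$label,
    x$n_subjects, x$n_raters
  ))
  invisible(x)
}

#' 95% limits of agreement from a difference sample
#'
#' `mean(values) +/- 1.96 * sd(values)` with the sample (n-1) standard
#' deviation. `values` may be raw differences (degrees) or percent ratios.
#'
#' @param values Numeric vector, length >= 2.
#' @return Named numeric `c(low, high)`.
#' @export
loa_from_differences <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  m <- mean(values)
  s <- sd(values)
  c(low = m - 1.96 * s, high = m + 1.96 * s)
}

#' Bland-Altman agreement analysis with bias-type handling
#'
#' Compares an instrument against a gold standard on paired measurements.
#' Differences are `instrument - gold`, means are `(instrument + gold) / 2`.
#' A *fixed* bias is declared when 0 lies outside the confidence interval of
#' the mean difference; a *proportional* bias is declared when the
#' correlation between difference and mean (gamma) is significant at
#' `alpha`. When a proportional bias is present, the difference variable is
#' replaced by its percent ratio to the mean, `100 * d / m`, and the central
#' bias and 95% limits of agreement are reported on that percent scale.
#'
#' @param instrument,gold Paired numeric vectors of equal length (n >= 3).
#' @param alpha Significance level for the proportional-bias test and the
#'   mean-difference CI.
#' @param ci_method `"t"` (default) for a t-based CI of the mean difference,
#'   `"z"` for a normal-quantile CI.
#' @return Object of class `bland_altman_result`: list with `n`,
#'   `mean_difference`, `ci_low`, `ci_high` (degrees), `gamma`, `p_gamma`,
#'   `fixed_bias`, `proportional_bias`, `bias_type` (`"none"`, `"fixed"`,
#'   `"proportional"` or `"both"`), `bias` (central bias on the LOA scale),
#'   `sd_difference`, `loa_low`, `loa_high` and `loa_units` (`"degrees"` or
#'   `"percent"`).
#' @examples
#' gold <- seq(40, 110, length.out = 42)
#' ba <- bland_altman(1.4375 * gold, gold)
#' ba$bias # mean percent ratio, about 35.9
#' @export
bland_altman <- function(instrument, gold, alpha = 0.05,
                         ci_method = c("t", "z")) {
  ci_method <- match.arg(ci_method)
  instrument <- as.numeric(instrument)
  gold <- as.numeric(gold)
  if (length(instrument) != length(gold)) {
    stop("instrument and gold must have equal length", call. = FALSE)
  }
  n <- length(instrument)
  if (n < 3L || anyNA(instrument) || anyNA(gold)) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  d <- instrument - gold
  m <- (instrument + gold) / 2

  mean_d <- mean(d)
  sd_d <- sd(d)
  q <- if (ci_method == "t") qt(1 - alpha / 2, n - 1) else qnorm(1 - alpha / 2)
  half <- q * sd_d / sqrt(n)
  ci <- c(mean_d - half, mean_d + half)
  fixed <- ci[1] > 0 || ci[2] < 0

  scale_ref <- sd(c(d, m)) + mean(abs(c(d, m))) + 1
  if (sd_d / scale_ref < 1e-12 || sd(m) / scale_ref < 1e-12) {
    gamma <- NA_real_
    p_gamma <- NA_real_
    proportional <- FALSE
  } else {
    ct <- cor.test(d, m)
    gamma <- unname(ct$estimate)
    p_gamma <- ct$p.value
    proportional <- is.finite(p_gamma) && p_gamma < alpha
  }

  bias_type <- if (fixed && proportional) {
    "both"
  } else if (proportional) {
    "proportional"
  } else if (fixed) {
    "fixed"
  } else {
    "none"
  }

  if (proportional) {
    if (any(abs(m) < .Machine$double.eps^0.5)) {
      stop(
        "zero mean pair: percent-ratio limits of agreement undefined when ",
        "(instrument + gold)/2 = 0",
        call. = FALSE
      )
    }
    ratio <- 100 * d / m
    bias <- mean(ratio)
    sd_loa <- sd(ratio)
    loa <- loa_from_differences(ratio)
    loa_units <- "percent"
  } else {
    bias <- mean_d
    sd_loa <- sd_d
    loa <- loa_from_differences(d)
    loa_units <- "degrees"
  }

  structure(
    list(
      n = n,
      mean_difference = mean_d,
      ci_low = ci[1],
      ci_high = ci[2],
      gamma = gamma,
      p_gamma = p_gamma,
      fixed_bias = fixed,
      proportional_bias = proportional,
      bias_type = bias_type,
      bias = bias,
      sd_difference = sd_loa,
      loa_low = unname(loa["low"]),
      loa_high = unname(loa["high"]),
      loa_units = loa_units,
      alpha = alpha,
      ci_method = ci_method
    ),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  unit <- if (x$loa_units == "percent") "%" else " deg"
  cat(sprintf(
    paste0(
      "Bland-Altman (n = %d): mean difference %.2f deg, %d%% CI (%.2f, %.2f)\n",
      "  gamma = %s, p = %s, bias: %s\n",
      "  central bias %.2f%s, 95%% LOA (%.2f, %.2f)%s\n"
    ),
    x$n, x$mean_difference, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
    ifelse(is.na(x$gamma), "NA", sprintf("%.2f", x$gamma)),
    ifelse(is.na(x$p_gamma), "NA", format.pval(x$p_gamma, digits = 3)),
    x$bias_type, x$bias, unit, x$loa_low, x$loa_high, unit
  ))
  invisible(x)
}
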