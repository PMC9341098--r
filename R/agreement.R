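# Method-comparison statistics. Differences are always taken as
# (first method - second method); by convention pass the estimate or
# uncorrected series first and the reference second, and every report
# labels the direction explicitly.

#' Paired sample for method comparison
#'
#' Validates and bundles two equal-length series of paired measurements.
#'
#' @param a First method's values (conventionally the estimate/uncorrected).
#' @param b Second method's values (conventionally the reference).
#' @param labels Optional per-pair identifiers.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(a, b, labels = NULL) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have equal length.", call. = FALSE)
  }
  keep <- stats::complete.cases(a, b)
  if (!all(keep)) {
    a <- a[keep]
    b <- b[keep]
    if (!is.null(labels)) labels <- labels[keep]
  }
  if (length(a) < 2) {
    stop("Need at least 2 complete pairs.", call. = FALSE)
  }
  if (is.null(labels)) labels <- as.character(seq_along(a))
  structure(list(labels = labels, a = a, b = b), class = "paired_sample")
}

#' Bland-Altman analysis
#'
#' Computes the mean difference, its standard deviation (n - 1 denominator)
#' and the limits of agreement d_bar +/- coverage * SD, with confidence
#' intervals for the mean difference (SE = SD/sqrt(n)) and for each limit
#' (SE = SD * sqrt(3/n), the classical Bland-Altman approximation;
#' `ci_method = "t"` swaps the normal multiplier for the Student-t
#' quantile).
#'
#' Differences are `a - b`. Either pass two vectors, or use
#' [ba_from_summary()] when only printed summaries (mean difference, SD, n)
#' are available.
#'
#' @param a,b Paired measurement vectors (a [paired_sample()] may be passed
#'   as `a`, with `b` omitted).
#' @param coverage Multiplier defining the limits, default 1.96 (95% LoA).
#' @param ci_method `"normal"` (multiplier = `coverage`) or `"t"`
#'   (Student-t quantile on n - 1 df) for the confidence intervals.
#' @return An object of class `bland_altman`: `n`, `mean_diff`, `sd_diff`,
#'   `mean_diff_ci`, `loa_lower`, `loa_upper`, `loa_lower_ci`,
#'   `loa_upper_ci`, `coverage`.
#' @examples
#' ba_from_summary(0.012, 0.486, 650)
#' @export
bland_altman <- function(a, b = NULL, coverage = 1.96,
                         ci_method = c("normal", "t")) {
  if (inherits(a, "paired_sample")) {
    s <- a
  } else {
    s <- paired_sample(a, b)
  }
  d <- s$a - s$b
  ba_from_summary(mean(d), stats::sd(d), length(d), coverage = coverage,
                  ci_method = ci_method)
}

#' @rdname bland_altman
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Sample standard deviation of the differences (n - 1
#'   denominator).
#' @param n Number of pairs.
#' @export
ba_from_summary <- function(mean_diff, sd_diff, n, coverage = 1.96,
                            ci_method = c("normal", "t")) {
  ci_method <- match.arg(ci_method)
  if (n < 2) stop("Need at least 2 pairs.", call. = FALSE)
  if (sd_diff < 0) stop("`sd_diff` must be non-negative.", call. = FALSE)
  z <- if (ci_method == "t") stats::qt(0.975, df = n - 1) else coverage
  half <- coverage * sd_diff
  se_mean <- sd_diff / sqrt(n)
  ci <- loa_confidence_intervals(mean_diff, sd_diff, n, coverage = coverage,
                                 ci_method = ci_method)
  structure(
    list(
      n = as.integer(n),
      mean_diff = mean_diff,
      sd_diff = sd_diff,
      mean_diff_ci = c(mean_diff - z * se_mean, mean_diff + z * se_mean),
      loa_lower = mean_diff - half,
      loa_upper = mean_diff + half,
      loa_lower_ci = ci$lower,
      loa_upper_ci = ci$upper,
      coverage = coverage
    ),
    class = "bland_altman"
  )
}

#' Confidence intervals for the limits of agreement
#'
#' Uses the approximate standard error SE(LoA) = SD * sqrt(3/n), with the
#' interval half-width `coverage * SE` (or the Student-t quantile on n - 1
#' df when `ci_method = "t"`).
#'
#' @inheritParams ba_from_summary
#' @return A list with elements `lower` and `upper`, each a length-2
#'   (lo, hi) interval for the corresponding limit of agreement.
#' @export
loa_confidence_intervals <- function(mean_diff, sd_diff, n, coverage = 1.96,
                                     ci_method = c("normal", "t")) {
  ci_method <- match.arg(ci_method)
  if (n < 2) stop("Need at least 2 pairs.", call. = FALSE)
  if (sd_diff < 0) stop("`sd_diff` must be non-negative.", call. = FALSE)
  z <- if (ci_method == "t") stats::qt(0.975, df = n - 1) else coverage
  se_loa <- sd_diff * sqrt(3 / n)
  lower <- mean_diff - coverage * sd_diff
  upper <- mean_diff + coverage * sd_diff
  list(lower = c(lower - z * se_loa, lower + z * se_loa),
       upper = c(upper - z * se_loa, upper + z * se_loa))
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  cat("Bland-Altman analysis (first method - second method)\n")
  cat(sprintf("  n pairs: %d\n", x$n))
  cat(sprintf("  mean difference: %s (95%% CI %s, %s)\n",
              f(x$mean_diff), f(x$mean_diff_ci[1]), f(x$mean_diff_ci[2])))
  cat(sprintf("  SD of differences: %s\n", f(x$sd_diff)))
  cat(sprintf("  lower LoA: %s (95%% CI %s, %s)\n",
              f(x$loa_lower), f(x$loa_lower_ci[1]), f(x$loa_lower_ci[2])))
  cat(sprintf("  upper LoA: %s (95%% CI %s, %s)\n",
              f(x$loa_upper), f(x$loa_upper_ci[1]), f(x$loa_upper_ci[2])))
  invisible(x)
}

#' Paired t-test from pairs or summaries
#'
#' t = d_bar / (SD / sqrt(n)) on n - 1 degrees of freedom, two-sided p from
#' the Student t distribution. Accepts either two paired vectors or the
#' printed summaries (mean difference, SD of differences, n).
#'
#' @param a,b Paired vectors, or leave `b = NULL` and supply summaries.
#' @param mean_diff,sd_diff,n Summary-mode inputs, used when `a` is missing.
#' @return A list with `t_stat`, `df`, `p_value`.
#' @examples
#' paired_t(mean_diff = 0.012, sd_diff = 0.486, n = 650)
#' @export
paired_t <- function(a, b = NULL, mean_diff = NULL, sd_diff = NULL, n = NULL) {
  if (!missing(a)) {
    s <- if (inherits(a, "paired_sample")) a else paired_sample(a, b)
    d <- s$a - s$b
    mean_diff <- mean(d)
    sd_diff <- stats::sd(d)
    n <- length(d)
  }
  if (is.null(mean_diff) || is.null(sd_diff) || is.null(n)) {
    stop("Supply either paired vectors or (mean_diff, sd_diff, n).",
         call. = FALSE)
  }
  if (n < 2) stop("Need at least 2 pairs.", call. = FALSE)
  if (sd_diff == 0) {
    stop("SD of differences is zero; the t-statistic is undefined.",
         call. = FALSE)
  }
  t_stat <- mean_diff / (sd_diff / sqrt(n))
  df <- n - 1
  list(t_stat = t_stat, df = as.integer(df),
       p_value = 2 * stats::pt(-abs(t_stat), df = df))
}

#' Intraclass correlation of absolute agreement
#'
#' Single-measure, absolute-agreement ICC from the two-way random-effects
#' model, ICC(A,1) (equivalently ICC(2,1)): with subjects as rows and the
#' two methods as columns,
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n),
#' where MSR, MSC, MSE are the rows, columns and error mean squares. The
#' confidence interval uses the standard F-distribution bounds with
#' Satterthwaite degrees of freedom.
#'
#' @param a,b Paired measurement vectors (or a [paired_sample()] as `a`).
#' @param conf_level Confidence level for the interval, default 0.95.
#' @return A list with `icc`, `ci` (lo, hi), and the mean squares
#'   (`msr`, `msc`, `mse`).
#' @export
icc_absolute <- function(a, b = NULL, conf_level = 0.95) {
  s <- if (inherits(a, "paired_sample")) a else paired_sample(a, b)
  m <- cbind(s$a, s$b)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) stop("Need at least 3 pairs for the ICC.", call. = FALSE)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    stop("Total variance is zero; the ICC is undefined.", call. = FALSE)
  }
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- ss_total - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse <= .Machine$double.eps * msr) {
    ci <- c(icc, icc)
  } else {
    a_ <- (k * icc) / (n * (1 - icc))
    b_ <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a_ * msc + b_ * mse)^2 /
      ((a_ * msc)^2 / (k - 1) + (b_ * mse)^2 / ((n - 1) * (k - 1)))
    f_lower <- stats::qf(1 - alpha / 2, n - 1, v)
    f_upper <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_lower * mse) /
      (f_lower * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_upper * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_upper * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci = ci, msr = msr, msc = msc, mse = mse)
}

#' Frequency of exceeding the coefficient of repeatability
#'
#' Percentage of pairs whose absolute difference strictly exceeds the
#' coefficient of repeatability (CR). The default CR of 0.052 mm^2 is the
#' published repeatability of FAZA for healthy eyes on the RTVue XR Avanti;
#' pass your own for other devices or metrics.
#'
#' @param method Values from the method under evaluation (e.g. FAZA
#'   corrected with estimated AL, or uncorrected FAZA).
#' @param reference Reference values (e.g. FAZA corrected with measured AL).
#' @param cr Coefficient of repeatability, same units as the measurements;
#'   positive.
#' @return Percentage of pairs with |method - reference| > cr.
#' @examples
#' cr_exceedance(c(0.31, 0.26), c(0.25, 0.25))
#' @export
cr_exceedance <- function(method, reference, cr = 0.052) {
  if (length(method) != length(reference)) {
    stop("`method` and `reference` must have equal length.", call. = FALSE)
  }
  if (length(method) < 1) stop("Need at least one pair.", call. = FALSE)
  if (cr <= 0) stop("`cr` must be positive.", call. = FALSE)
  100 * sum(abs(method - reference) > cr) / length(method)
}

#' Per-pair relative change against a reference
#'
#' 100 * |reference - other| / reference per pair, plus the maximum
#' relative (%) and maximum absolute change.
#'
#' @param reference Reference values; all strictly positive.
#' @param other Comparison values, same length.
#' @return A list with `percent` (per-pair %), `max_relative` (%),
#'   `max_absolute` (input units).
#' @examples
#' relative_change(c(0.2, 0.4), c(0.25, 0.38))
#' @export
relative_change <- function(reference, other) {
  if (length(reference) != length(other)) {
    stop("`reference` and `other` must have equal length.", call. = FALSE)
  }
  if (any(reference <= 0)) {
    stop("All `reference` values must be strictly positive.", call. = FALSE)
  }
  abs_change <- abs(reference - other)
  pct <- 100 * abs_change / reference
  list(percent = pct, max_relative = max(pct), max_absolute = max(abs_change))
}

#' Full agreement report for two methods
#'
#' Runs the complete method-comparison battery on one pair of series:
#' Bland-Altman with LoA confidence intervals, paired t-test, ICC of
#' absolute agreement, and optionally CR-exceedance and per-pair relative
#' change. Differences are `a - b`; pass the estimate/uncorrected series as
#' `a` and the reference as `b`.
#'
#' @inheritParams bland_altman
#' @param cr Coefficient of repeatability for the exceedance frequency, or
#'   `NULL` to skip.
#' @param with_relative_change If `TRUE`, report per-pair relative change of
#'   `a` against reference `b` (requires all `b` > 0).
#' @param labels Optional per-pair identifiers.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(a, b, coverage = 1.96, cr = NULL,
                             with_relative_change = FALSE, labels = NULL) {
  s <- if (inherits(a, "paired_sample")) a else paired_sample(a, b, labels)
  ba <- bland_altman(s, coverage = coverage)
  tt <- if (ba$sd_diff > 0) {
    paired_t(s)
  } else {
    list(t_stat = NA_real_, df = ba$n - 1L, p_value = NA_real_)
  }
  icc <- icc_absolute(s)
  rep <- list(
    direction = "first method - second method",
    bland_altman = ba,
    t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
    icc = icc$icc, icc_ci = icc$ci
  )
  if (!is.null(cr)) {
    rep$cr <- cr
    rep$cr_exceedance_pct <- cr_exceedance(s$a, s$b, cr = cr)
  }
  if (isTRUE(with_relative_change)) {
    rep$relative_change <- relative_change(s$b, s$a)
  }
  structure(rep, class = "agreement_report")
}

# Paper-style display convention: p to 3 decimals, floored at "< 0.005".
format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.005) "< 0.005" else formatC(p, digits = 3, format = "f")
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  ba <- x$bland_altman
  cat("Agreement report (differences:", x$direction, ")\n")
  cat(sprintf(
    "  Mean diff (95%% CI): %s (%s, %s)   SD: %s\n",
    f(ba$mean_diff), f(ba$mean_diff_ci[1]), f(ba$mean_diff_ci[2]), f(ba$sd_diff)))
  cat(sprintf(
    "  Lower LoA (95%% CI): %s (%s, %s)\n",
    f(ba$loa_lower), f(ba$loa_lower_ci[1]), f(ba$loa_lower_ci[2])))
  cat(sprintf(
    "  Upper LoA (95%% CI): %s (%s, %s)\n",
    f(ba$loa_upper), f(ba$loa_upper_ci[1]), f(ba$loa_upper_ci[2])))
  cat(sprintf("  t_stat (df): %s (%d)   P: %s\n",
              f(x$t_stat), x$df, format_p(x$p_value)))
  cat(sprintf("  ICC (95%% CI): %s (%s, %s)\n",
              f(x$icc), f(x$icc_ci[1]), f(x$icc_ci[2])))
  if (!is.null(x$cr_exceedance_pct)) {
    cat(sprintf("  |diff| > CR (%g): %.1f%% of pairs\n",
                x$cr, x$cr_exceedance_pct))
  }
  if (!is.null(x$relative_change)) {
    cat(sprintf("  relative change: max %.1f%% (absolute max %.3g)\n",
                x$relative_change$max_relative,
                x$relative_change$max_absolute))
  }
  invisible(x)
}

# Serializable (full-precision) view of an agreement report.
report_to_list <- function(x) {
  stopifnot(inherits(x, "agreement_report"))
  ba <- x$bland_altman
  out <- list(
    direction = x$direction,
    n = ba$n,
    mean_diff = ba$mean_diff,
    mean_diff_ci = ba$mean_diff_ci,
    sd_diff = ba$sd_diff,
    loa_lower = ba$loa_lower,
    loa_lower_ci = ba$loa_lower_ci,
    loa_upper = ba$loa_upper,
    loa_upper_ci = ba$loa_upper_ci,
    coverage = ba$coverage,
    t_stat = x$t_stat,
    df = x$df,
    p_value = x$p_value,
    icc = x$icc,
    icc_ci = x$icc_ci
  )
  if (!is.null(x$cr_exceedance_pct)) {
    out$cr <- x$cr
    out$cr_exceedance_pct <- x$cr_exceedance_pct
  }
  if (!is.null(x$relative_change)) out$relative_change <- x$relative_change
  out
}
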