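#' Pearson correlation with large-sample standard error
#'
#' The product-moment correlation between self-reported and reference values
#' measures the strength of their (linear) association; it is sensitive to
#' random but not purely systematic reporting error. The standard error is
#' the large-sample form `sqrt((1 - r^2) / (n - 2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return List with elements `r` and `se`.
#' @export
pearson_with_se <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop_domain("pearson_with_se requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_domain("correlation undefined: constant vector")
  r <- stats::cor(x, y)
  list(r = r, se = sqrt((1 - r^2) / (n - 2)))
}

#' Paired t-test for mean over- or under-reporting
#'
#' Tests whether the mean difference (self-report minus reference) is zero,
#' the screen for systematic over-/under-reporting. Degenerate difference
#' vectors (zero variance) are handled analytically: a nonzero constant
#' difference gives p = 0, an all-zero difference vector gives p = 1; both
#' are flagged.
#'
#' @param sample A [paired_sample()] with n >= 2.
#' @return List with `mean_diff`, `sd_diff`, `p` (two-sided) and `degenerate`.
#' @export
mean_difference_test <- function(sample) {
  d <- differences(sample)
  if (length(d) < 2L) stop_domain("mean_difference_test requires n >= 2")
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    return(list(mean_diff = m, sd_diff = 0,
                p = if (m == 0) 1 else 0, degenerate = TRUE))
  }
  p <- stats::t.test(d)$p.value
  list(mean_diff = m, sd_diff = s, p = p, degenerate = FALSE)
}

#' Bland-Altman 95% limits of agreement, raw and reference-SD-scaled
#'
#' The limits `mean(d) -/+ 1.96 sd(d)` of the paired differences give the
#' typical range of individual reporting errors. Because purely random error
#' attenuates associations according to the error SD relative to the SD of
#' true values, the bounds are also reported divided by the reference SD,
#' putting variables with different units on a common, attenuation-relevant
#' scale. Bounds are not centred at zero: a mean reporting bias shifts both.
#'
#' @param sample A [paired_sample()] with n >= 3.
#' @return List with `lower`, `upper`, `scaled_lower`, `scaled_upper`.
#' @export
limits_of_agreement <- function(sample) {
  d <- differences(sample)
  if (length(d) < 3L) stop_domain("limits_of_agreement requires n >= 3")
  sd_ref <- stats::sd(sample$reference)
  lo <- mean(d) - 1.96 * stats::sd(d)
  hi <- mean(d) + 1.96 * stats::sd(d)
  if (sd_ref == 0)
    stop_domain("scaled limits undefined: reference values are constant")
  list(lower = lo, upper = hi,
       scaled_lower = lo / sd_ref, scaled_upper = hi / sd_ref)
}

#' Intraclass correlation ICC(1,1), one-way random effects
#'
#' Treats the self-report and reference value of each participant as two
#' single ratings in a one-way random-effects model and computes
#' `(MS_between - MS_within) / (MS_between + (k - 1) MS_within)` with k = 2.
#' Unlike the Pearson correlation, the ICC is reduced by systematic as well
#' as random disagreement: a constant shift between the two sources lowers
#' the ICC but leaves r unchanged, so the r-ICC gap flags systematic error.
#' The standard error is the large-sample form, which for k = 2 reduces to
#' `(1 - icc^2) / sqrt(n - 1)`.
#'
#' @param sample A [paired_sample()] with n >= 3.
#' @return List with `icc` and `se`.
#' @export
icc_1_1 <- function(sample) {
  x <- sample$self_report; y <- sample$reference
  n <- length(x)
  if (n < 3L) stop_domain("icc_1_1 requires n >= 3")
  k <- 2
  m <- (x + y) / 2
  grand <- mean(m)
  msb <- k * sum((m - grand)^2) / (n - 1)
  msw <- sum((x - m)^2 + (y - m)^2) / (n * (k - 1))
  if (msb + msw == 0)
    stop_domain("ICC undefined: all values identical")
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  se <- sqrt(2 * (1 - icc)^2 * (1 + (k - 1) * icc)^2 / (k * (k - 1) * (n - 1)))
  list(icc = icc, se = se)
}

#' Reporting-error profile across quintiles of the reference values
#'
#' Partitions participants at the empirical 20/40/60/80 percentiles of the
#' reference values (ties fall in the lower stratum) and summarises the
#' reporting error (self-report minus reference) within each stratum; a
#' one-way ANOVA tests equality of the stratum mean errors, the test for
#' differential (truth-dependent) reporting error. Unequal stratum sizes are
#' expected when the reference values are heavily tied.
#'
#' @param sample A [paired_sample()] with n >= 10.
#' @return Object of class `quintile_error_profile`: a list with
#'   `quintile_edges`, a data frame `strata` (`n`, `mean_error`, `sd_error`),
#'   `anova_p` and `degenerate` (TRUE when the ANOVA is undefined, e.g.
#'   error-free data). Strata with n < 2 have `sd_error = NA` and are
#'   excluded from the ANOVA.
#' @export
quintile_error_profile <- function(sample) {
  if (sample$n < 10L) stop_domain("quintile_error_profile requires n >= 10")
  err <- differences(sample)
  edges <- stats::quantile(sample$reference, c(.2, .4, .6, .8), names = FALSE)
  uedges <- unique(edges)
  if (length(uedges) < length(edges))
    warning("tied quantiles collapsed: fewer than 5 strata")
  stratum <- cut(sample$reference, breaks = c(-Inf, uedges, Inf),
                 labels = FALSE, right = TRUE)
  ns <- tabulate(stratum, nbins = length(uedges) + 1L)
  strata <- data.frame(
    stratum = seq_along(ns), n = ns,
    mean_error = as.numeric(tapply(err, factor(stratum, seq_along(ns)), mean)),
    sd_error = as.numeric(tapply(err, factor(stratum, seq_along(ns)), stats::sd)))
  keep <- stratum %in% strata$stratum[strata$n >= 2L]
  f <- factor(stratum[keep])
  degenerate <- nlevels(f) < 2L || stats::var(err[keep]) == 0
  anova_p <- if (degenerate) NA_real_ else {
    stats::anova(stats::lm(err[keep] ~ f))[["Pr(>F)"]][1]
  }
  structure(list(quintile_edges = uedges, strata = strata,
                 anova_p = anova_p, degenerate = degenerate,
                 variable = sample$meta$name),
            class = "quintile_error_profile")
}

#' @export
print.quintile_error_profile <- function(x, ...) {
  cat("<quintile_error_profile> ", x$variable, "\n", sep = "")
  print(x$strata, row.names = FALSE)
  cat("one-way ANOVA p =",
      if (x$degenerate) "NA (degenerate)" else format.pval(x$anova_p), "\n")
  invisible(x)
}

#' Full quantitative agreement summary for one variable
#'
#' Assembles, for a quantitative variable, the row of a validation-study
#' agreement table: n, means and SDs of both sources, the mean difference
#' with its paired t-test, raw and reference-SD-scaled 95% limits of
#' agreement, ICC(1,1) and the Pearson correlation, each with standard
#' errors. With only n = 2 pairs the record is produced but flagged
#' unreliable (limits of agreement and ICC need n >= 3).
#'
#' @param sample A [paired_sample()] for a quantitative variable.
#' @return Object of class `agreement_summary` (a one-row-like list; see
#'   [as.data.frame.agreement_summary()]).
#' @export
summarize_agreement <- function(sample) {
  if (sample$meta$kind != "quantitative")
    stop_domain("summarize_agreement applies to quantitative variables only")
  mt <- mean_difference_test(sample)
  unreliable <- sample$n < 3L
  loa <- if (unreliable) list(lower = NA_real_, upper = NA_real_,
                              scaled_lower = NA_real_, scaled_upper = NA_real_)
         else limits_of_agreement(sample)
  icc <- if (unreliable) list(icc = NA_real_, se = NA_real_) else icc_1_1(sample)
  pr <- if (unreliable || stats::sd(sample$self_report) == 0 ||
            stats::sd(sample$reference) == 0)
    list(r = NA_real_, se = NA_real_) else pearson_with_se(sample$self_report,
                                                           sample$reference)
  structure(list(
    variable = sample$meta$name, units = sample$meta$units, n = sample$n,
    mean_self = mean(sample$self_report), sd_self = stats::sd(sample$self_report),
    mean_ref = mean(sample$reference), sd_ref = stats::sd(sample$reference),
    mean_diff = mt$mean_diff, sd_diff = mt$sd_diff, t_p = mt$p,
    loa_lower = loa$lower, loa_upper = loa$upper,
    scaled_loa_lower = loa$scaled_lower, scaled_loa_upper = loa$scaled_upper,
    icc = icc$icc, icc_se = icc$se,
    pearson_r = pr$r, pearson_se = pr$se,
    degenerate = mt$degenerate, unreliable = unreliable
  ), class = "agreement_summary")
}

#' @export
#' @rdname summarize_agreement
#' @param x An `agreement_summary`.
#' @param ... Unused.
as.data.frame.agreement_summary <- function(x, ...) {
  as.data.frame(unclass(x)[c("variable", "units", "n", "mean_self", "sd_self",
                             "mean_ref", "sd_ref", "mean_diff", "sd_diff",
                             "t_p", "loa_lower", "loa_upper",
                             "scaled_loa_lower", "scaled_loa_upper",
                             "icc", "icc_se", "pearson_r", "pearson_se")],
                stringsAsFactors = FALSE)
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("<agreement_summary> ", x$variable, " (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  mean self %.3f (SD %.3f); mean ref %.3f (SD %.3f)\n",
              x$mean_self, x$sd_self, x$mean_ref, x$sd_ref))
  cat(sprintf("  mean diff %.3f (SD %.3f), t-test p = %s\n",
              x$mean_diff, x$sd_diff, format.pval(x$t_p)))
  cat(sprintf("  95%% LoA (%.3f, %.3f); scaled (%.3f, %.3f)\n",
              x$loa_lower, x$loa_upper, x$scaled_loa_lower, x$scaled_loa_upper))
  cat(sprintf("  ICC(1,1) %.3f (SE %.3f); Pearson r %.3f (SE %.3f)\n",
              x$icc, x$icc_se, x$pearson_r, x$pearson_se))
  invisible(x)
}
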