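#' Category means of self-report and reference values
#'
#' Groups participants by pre-specified categories of the self-reported
#' value and computes, per category, the mean of both members plus a 95%
#' confidence interval for the reference mean (`mean +/- 1.96 SD/sqrt(n)`).
#' Plotting reference category means against self-report category means
#' (with the line of equality) shows where measurements run higher or lower
#' than self-reports suggest, and is the basis of the non-parametric
#' regression dilution ratio.
#'
#' Categories are half-open intervals `[e_i, e_{i+1})` with the last closed;
#' `edges` is the full breaks vector (outer bounds included, possibly
#' infinite). When `edges` is `NULL`, empirical quintile breaks of the
#' self-reported values are used.
#'
#' @param sample A [paired_sample()].
#' @param edges Strictly increasing numeric breaks (length k + 1 for k
#'   categories), or `NULL` for self-report quintiles.
#' @return Object of class `category_means`: data frame `table` with columns
#'   `category`, `n`, `mean_self`, `mean_ref`, `ci_lo`, `ci_hi`, plus the
#'   resolved `edges` and the indices of any `empty` categories (excluded
#'   from range computations, with a warning).
#' @export
category_means <- function(sample, edges = NULL) {
  x <- sample$self_report; y <- sample$reference
  if (is.null(edges)) {
    edges <- unique(stats::quantile(x, seq(0, 1, 0.2), names = FALSE))
    if (length(edges) < 3L)
      stop_domain("cannot form >= 2 default categories: self-report values ",
                  "too heavily tied")
  }
  if (any(diff(edges) <= 0)) stop_domain("edges must be strictly increasing")
  k <- length(edges) - 1L
  cat_idx <- findInterval(x, edges, rightmost.closed = TRUE)
  if (any(cat_idx < 1L | cat_idx > k))
    stop_domain("self-report values outside the category edges for '",
                sample$meta$name, "'")
  n <- tabulate(cat_idx, nbins = k)
  empty <- which(n == 0L)
  if (length(empty))
    warning(length(empty), " empty categor",
            if (length(empty) == 1L) "y" else "ies",
            " excluded from range computation")
  f <- factor(cat_idx, levels = seq_len(k))
  ms <- as.numeric(tapply(x, f, mean))
  mr <- as.numeric(tapply(y, f, mean))
  sr <- as.numeric(tapply(y, f, stats::sd))
  half <- 1.96 * sr / sqrt(n)
  structure(list(
    table = data.frame(category = seq_len(k), n = n, mean_self = ms,
                       mean_ref = mr, ci_lo = mr - half, ci_hi = mr + half),
    edges = edges, empty = empty, variable = sample$meta$name
  ), class = "category_means")
}

#' @export
print.category_means <- function(x, ...) {
  cat("<category_means> ", x$variable, ", edges: ",
      paste(signif(x$edges, 4), collapse = " "), "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Non-parametric regression dilution ratio (range-of-means estimator)
#'
#' The RDR is estimated as the range of the reference category means divided
#' by the range of the self-report category means (maxima and minima taken
#' over categories, not individuals). It estimates the factor by which a
#' linear log-relative-risk coefficient fitted to self-reported exposure is
#' attenuated relative to the coefficient on true exposure; it reflects the
#' combined effect of random error (pushing the RDR below 1) and systematic
#' scale error (which can push it above 1, as when under-reporting grows
#' with the true value). Perfectly reported data give RDR = 1.
#'
#' @param category_result A [category_means()] result, or a
#'   [paired_sample()] (in which case `edges` is forwarded).
#' @param edges Optional category breaks when a sample is given.
#' @return The RDR (dimensionless scalar).
#' @export
rdr_point <- function(category_result, edges = NULL) {
  if (inherits(category_result, "paired_sample"))
    category_result <- category_means(category_result, edges)
  stopifnot(inherits(category_result, "category_means"))
  tab <- category_result$table[category_result$table$n > 0L, ]
  if (nrow(tab) < 2L)
    stop_domain("RDR undefined: fewer than 2 non-empty categories")
  denom <- max(tab$mean_self) - min(tab$mean_self)
  if (denom <= 0) stop_domain("RDR undefined: zero self-report mean range")
  (max(tab$mean_ref) - min(tab$mean_ref)) / denom
}

#' Percentile-bootstrap confidence interval for the RDR
#'
#' Resamples participants (paired rows together, preserving the error
#' structure) with replacement, recomputes the range-of-means RDR on each
#' replicate with the same category edges, and returns the 2.5th and 97.5th
#' percentiles of the bootstrap distribution. Replicates in which any
#' originally non-empty category empties, or the self-report mean range
#' collapses, are discarded and counted; more than 50% discarded is an
#' error. Results are reproducible for a fixed seed.
#'
#' @param sample A [paired_sample()].
#' @param edges Category breaks (see [category_means()]); `NULL` resolves
#'   self-report quintiles once from the full sample, which are then held
#'   fixed across replicates.
#' @param n_boot Number of bootstrap replicates (>= 1000 recommended).
#' @param seed Integer RNG seed.
#' @return Object of class `rdr_result`: list with `rdr`, `ci` (length-2),
#'   `category_means`, `n_boot`, `n_discarded`, `seed`.
#' @export
rdr_bootstrap_ci <- function(sample, edges = NULL, n_boot = 2000, seed = 1) {
  cm <- category_means(sample, edges)
  point <- rdr_point(cm)
  k <- length(cm$edges) - 1L
  occupied <- which(cm$table$n > 0L)
  cat_idx <- findInterval(sample$self_report, cm$edges, rightmost.closed = TRUE)
  n <- sample$n
  xy <- cbind(sample$self_report, sample$reference)
  stats_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cnt <- tabulate(cat_idx[idx], nbins = k)
      if (any(cnt[occupied] == 0L)) return(NA_real_)
      sums <- rowsum(xy[idx, , drop = FALSE], cat_idx[idx])
      ms <- sums[, 1] / cnt[cnt > 0L]
      mr <- sums[, 2] / cnt[cnt > 0L]
      denom <- max(ms) - min(ms)
      if (denom <= 0) return(NA_real_)
      (max(mr) - min(mr)) / denom
    }, numeric(1))
  })
  discarded <- sum(is.na(stats_boot))
  if (discarded > n_boot / 2)
    stop_domain("bootstrap failed: ", discarded, " of ", n_boot,
                " replicates discarded (empty categories or collapsed range); ",
                "use wider categories or more data")
  ci <- stats::quantile(stats_boot, c(.025, .975), na.rm = TRUE, names = FALSE)
  structure(list(rdr = point, ci = ci, category_means = cm,
                 n_boot = n_boot, n_discarded = discarded, seed = seed),
            class = "rdr_result")
}

#' @export
print.rdr_result <- function(x, ...) {
  cat(sprintf("<rdr_result> RDR = %.3f (95%% bootstrap CI %.3f-%.3f; %d replicates, %d discarded)\n",
              x$rdr, x$ci[1], x$ci[2], x$n_boot, x$n_discarded))
  invisible(x)
}

#' Regression-slope cross-check for the RDR
#'
#' The least-squares slope of reference on self-report, a parametric
#' estimate of the same attenuation factor under a linear conditional mean.
#' Provided as a cross-check; the headline statistic is the non-parametric
#' [rdr_point()].
#'
#' @param sample A [paired_sample()].
#' @return Slope (dimensionless scalar).
#' @export
rdr_slope <- function(sample) {
  unname(stats::coef(stats::lm(sample$reference ~ sample$self_report))[2])
}

#' Correct a relative risk for regression dilution
#'
#' A relative risk estimated per unit of error-prone self-reported exposure
#' is de-attenuated to the per-unit-true-exposure scale by
#' `exp(log(rr) / rdr)`. An RDR of 1 leaves the estimate unchanged; a null
#' RR of 1 is a fixed point. Valid for linear (log-linear) associations in
#' univariate analyses; power lost to reporting error is not restored.
#'
#' @param rr Relative risk, > 0.
#' @param rdr Regression dilution ratio, > 0.
#' @return Corrected relative risk.
#' @export
#' @examples
#' correct_relative_risk(1.5, 0.5)  # 2.25 per unit true exposure
correct_relative_risk <- function(rr, rdr) {
  if (any(rr <= 0) || any(rdr <= 0))
    stop_domain("rr and rdr must be positive")
  exp(log(rr) / rdr)
}

#' Effective sample size under exposure reporting error
#'
#' The squared correlation between reported and true (reference) exposure
#' approximates the effective sample size as a proportion of the actual
#' sample size; the complement is the percent power-equivalent loss, which
#' RDR-type corrections cannot recover.
#'
#' @param r Correlation, |r| <= 1.
#' @return List with `fraction` (= r^2) and `percent_reduction`
#'   (`100 (1 - r^2)`, rounded to the nearest integer percent for display).
#' @export
#' @examples
#' effective_sample_fraction(0.52)$percent_reduction  # 73
effective_sample_fraction <- function(r) {
  if (any(abs(r) > 1)) stop_domain("|r| must not exceed 1")
  list(fraction = r^2, percent_reduction = round(100 * (1 - r^2)))
}

#' Percent attenuation implied by an RDR
#'
#' `100 (1 - rdr)`: an RDR of 0.5 means the log relative risk is attenuated
#' by 50% towards zero; an RDR above 1 gives a negative value (inflation).
#'
#' @param rdr Regression dilution ratio.
#' @return Percent attenuation (may be negative).
#' @export
attenuation_percent <- function(rdr) {
  100 * (1 - rdr)
}
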