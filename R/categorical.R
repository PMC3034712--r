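kappa_band <- function(kappa, tol = 1e-9) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0.2 + tol) "poor"
  else if (kappa <= 0.4 + tol) "fair"
  else if (kappa <= 0.6 + tol) "moderate"
  else if (kappa <= 0.8 + tol) "substantial"
  else "excellent"
}

#' Cohen's kappa and raw percentage agreement
#'
#' Cross-tabulates paired categorical reports and computes the raw
#' percentage agreement (100 x trace/total) and Cohen's kappa, the
#' proportion of agreement over and above chance:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_e` from the marginal products.
#' Kappa is banded by the usual convention: <= 0.2 poor, (0.2, 0.4] fair,
#' (0.4, 0.6] moderate, (0.6, 0.8] substantial, > 0.8 excellent
#' ("almost perfect"). The p-value against chance agreement is the
#' large-sample z-test of kappa = 0 (Fleiss null standard error).
#'
#' @param self_report,reference Vectors of category labels (equal length,
#'   shared label set), or a [paired_sample()] for a binary variable as the
#'   first argument.
#' @return Object of class `categorical_agreement`: list with `table`,
#'   `percent_agreement`, `kappa`, `kappa_band`, `p_vs_chance`, `n`.
#'   If both raters are constant on the same label, kappa is `NA`
#'   (`p_e = 1`) but percent agreement is still reported.
#' @export
#' @examples
#' kappa_agreement(c("yes", "yes", "no", "no"), c("yes", "no", "no", "no"))
kappa_agreement <- function(self_report, reference = NULL) {
  if (inherits(self_report, "paired_sample")) {
    s <- self_report
    labs <- s$meta$levels %||% sort(unique(c(s$self_report, s$reference)))
    self_report <- labs[s$self_report]
    reference <- labs[s$reference]
  }
  stopifnot(length(self_report) == length(reference))
  labs <- sort(unique(c(as.character(self_report), as.character(reference))))
  tab <- table(factor(self_report, labs), factor(reference, labs),
               dnn = c("self_report", "reference"))
  n <- sum(tab)
  if (n < 1L) stop_domain("empty contingency table")
  po <- sum(diag(tab)) / n
  prow <- rowSums(tab) / n
  pcol <- colSums(tab) / n
  pe <- sum(prow * pcol)
  if (pe >= 1) {
    kap <- NA_real_; p <- NA_real_
  } else {
    kap <- (po - pe) / (1 - pe)
    # Fleiss large-sample SE of kappa under the null of chance agreement
    se0 <- sqrt(pe + pe^2 - sum(prow * pcol * (prow + pcol))) /
      ((1 - pe) * sqrt(n))
    z <- kap / se0
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(table = tab, n = n, percent_agreement = 100 * po,
                 kappa = kap, kappa_band = kappa_band(kap), p_vs_chance = p),
            class = "categorical_agreement")
}

#' @export
print.categorical_agreement <- function(x, ...) {
  cat(sprintf("<categorical_agreement> %.1f%% agreement; kappa = %s (%s), p vs chance = %s\n",
              x$percent_agreement,
              if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa),
              x$kappa_band %||% "NA",
              format.pval(x$p_vs_chance)))
  print(x$table)
  invisible(x)
}

#' Association between an ordinal self-report and a quantitative reference
#'
#' Ordinal self-reported categories (e.g. relative body size, clothes size)
#' are scored by their integer group ranks (1 for the lowest category, 2 for
#' the next, and so on) and related to the quantitative reference
#' measurement by the Spearman rank correlation (midranks for ties) and a
#' p-value for linear trend from the least-squares regression of the
#' reference values on the rank scores. Per-level means and standard errors
#' of the reference are returned for plotting.
#'
#' @param sample A [paired_sample()] whose self-report holds integer level
#'   ranks (ordinal variable) and whose reference is quantitative.
#' @return Object of class `ordinal_association`: list with `levels` (data
#'   frame: `level`, `label`, `n`, `mean_ref`, `se_ref`), `spearman_r`,
#'   `trend_p`, `n`.
#' @export
ordinal_association <- function(sample) {
  ranks <- sample$self_report
  y <- sample$reference
  lev <- sort(unique(ranks))
  if (length(lev) < 2L)
    stop_domain("ordinal association undefined: single occupied level")
  labels <- sample$meta$levels
  per <- data.frame(
    level = lev,
    label = if (!is.null(labels) && max(lev) <= length(labels))
      labels[lev] else as.character(lev),
    n = as.integer(table(factor(ranks, lev))),
    mean_ref = as.numeric(tapply(y, factor(ranks, lev), mean)),
    se_ref = as.numeric(tapply(y, factor(ranks, lev),
                               function(v) stats::sd(v) / sqrt(length(v)))),
    stringsAsFactors = FALSE)
  rho <- stats::cor(ranks, y, method = "spearman")
  fit <- summary(stats::lm(y ~ ranks))
  trend_p <- fit$coefficients["ranks", "Pr(>|t|)"]
  structure(list(levels = per, spearman_r = rho, trend_p = trend_p,
                 n = sample$n, variable = sample$meta$name),
            class = "ordinal_association")
}

#' @export
print.ordinal_association <- function(x, ...) {
  cat(sprintf("<ordinal_association> %s: Spearman r = %.3f, trend p = %s (n = %d)\n",
              x$variable, x$spearman_r, format.pval(x$trend_p), x$n))
  print(x$levels, row.names = FALSE)
  invisible(x)
}

# Null log-probability of a contingency table given fixed margins
log_prob_table <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Exact subgroup comparison of a categorical outcome
#'
#' Tests whether a per-participant categorical outcome (e.g. missing
#' yes/no, or an agreement band) differs across subgroup levels (e.g.
#' childhood social class, mother still alive). For a 2x2 table the
#' two-sided Fisher exact p-value is returned; for larger tables an
#' exact-conditional p-value is approximated by Monte-Carlo sampling of
#' tables with the observed margins (null probabilities summed over tables
#' no more probable than the observed one), with its Monte-Carlo standard
#' error. All-zero rows or columns are dropped with a warning.
#'
#' @param outcome Categorical outcome per participant.
#' @param factor Subgroup label per participant.
#' @param n_perm Monte-Carlo tables for larger-than-2x2 cases (>= 10000
#'   recommended).
#' @param seed RNG seed for the Monte-Carlo sampler.
#' @return List with `p`, `mc_se` (0 for the exact 2x2 path), `method` and
#'   `table`.
#' @export
subgroup_comparison <- function(outcome, factor, n_perm = 10000, seed = 1) {
  tab <- table(outcome, factor)
  if (sum(tab) < 2L) stop_domain("subgroup_comparison requires total n >= 2")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero row(s)/column(s) from the contingency table")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (any(dim(tab) < 2L))
    stop_domain("table degenerate after dropping empty margins")
  if (all(dim(tab) == 2L)) {
    p <- stats::fisher.test(tab)$p.value
    return(list(p = p, mc_se = 0, method = "fisher_exact_2x2", table = tab))
  }
  obs <- log_prob_table(tab)
  hits <- with_seed(seed, {
    sims <- stats::r2dtable(n_perm, rowSums(tab), colSums(tab))
    sum(vapply(sims, log_prob_table, numeric(1)) <= obs + 1e-7)
  })
  p <- (hits + 1) / (n_perm + 1)
  list(p = p, mc_se = sqrt(p * (1 - p) / n_perm),
       method = "monte_carlo_fixed_margins", table = tab)
}
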