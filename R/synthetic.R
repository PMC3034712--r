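#' Generative error model for a synthetic paired validation variable
#'
#' Encodes the linear differential reporting-error model
#' `self_report = a + b * T + eps`, `reference = T + u`, with truth
#' `T ~ Normal(mu_T, sigma_T^2)` (optionally log-normal for skewed
#' variables), random reporting error `eps ~ Normal(0, sigma_eps^2)` and
#' optional reference-side ("alloyed gold standard") error
#' `u ~ Normal(0, sigma_u^2)`, all mutually independent. `b < 1` and/or
#' `a < 0` encode under-reporting that grows with the true value, the
#' pattern seen for self-reported weight.
#'
#' @param n Sample size.
#' @param seed Integer RNG seed; all generators are pure functions of
#'   (spec, seed).
#' @param mu_T,sigma_T Mean and SD of the truth distribution.
#' @param a Additive systematic offset (value units).
#' @param b Multiplicative systematic slope (dimensionless, nonzero).
#' @param sigma_eps SD of the random reporting error.
#' @param sigma_u SD of the reference-side error (0 = gold standard).
#' @param name Variable name for the attached metadata.
#' @param units Units for the attached metadata.
#' @param truth_dist `"normal"` or `"lognormal"` (meanlog `mu_T`, sdlog
#'   `sigma_T`).
#' @param round_to_integer Round the self-report to whole units (digit
#'   heaping in whole-year ages); off by default.
#' @return Object of class `error_model_spec`.
#' @seealso [simulate_quantitative()], [attenuation_lambda()]
#' @export
error_model_spec <- function(n, seed, mu_T = 0, sigma_T = 1, a = 0, b = 1,
                             sigma_eps = 0, sigma_u = 0, name = "x",
                             units = "", truth_dist = c("normal", "lognormal"),
                             round_to_integer = FALSE) {
  truth_dist <- match.arg(truth_dist)
  if (sigma_T < 0 || sigma_eps < 0 || sigma_u < 0)
    stop_domain("sigma parameters must be >= 0")
  if (b == 0) stop_domain("slope b must be nonzero")
  if (n < 1) stop_domain("n must be >= 1")
  structure(list(n = as.integer(n), seed = seed, mu_T = mu_T, sigma_T = sigma_T,
                 a = a, b = b, sigma_eps = sigma_eps, sigma_u = sigma_u,
                 name = name, units = units, truth_dist = truth_dist,
                 round_to_integer = isTRUE(round_to_integer)),
            class = "error_model_spec")
}

#' Analytic attenuation factor of an error model
#'
#' Under the linear model `report = a + b T + eps` the slope of the
#' conditional mean of truth (hence reference) on report is
#' `lambda = b sigma_T^2 / (b^2 sigma_T^2 + sigma_eps^2)` =
#' Cov(T, report)/Var(report). This is the value the range-of-means RDR
#' estimator converges to on large samples, regardless of the offset `a`
#' and of reference-side error `sigma_u` (which is independent of the
#' report). It can exceed 1 when a compressive scale error (b < 1)
#' dominates the random error.
#'
#' @param spec An [error_model_spec()].
#' @return The attenuation factor lambda (dimensionless).
#' @export
attenuation_lambda <- function(spec) {
  with(spec, b * sigma_T^2 / (b^2 * sigma_T^2 + sigma_eps^2))
}

draw_truth <- function(spec) {
  if (spec$truth_dist == "lognormal")
    stats::rlnorm(spec$n, spec$mu_T, spec$sigma_T)
  else stats::rnorm(spec$n, spec$mu_T, spec$sigma_T)
}

#' Simulate a quantitative paired validation variable
#'
#' Draws a seeded synthetic cohort from the spec's error model and returns
#' the paired sample with the analytic attenuation [attenuation_lambda()]
#' attached as ground truth (`attr(, "lambda")`), along with the truth
#' vector (`attr(, "truth")`) for oracle checks.
#'
#' @param spec An [error_model_spec()].
#' @return A [paired_sample()] (quantitative) with attributes `lambda`,
#'   `truth` and `spec`.
#' @export
#' @examples
#' s <- simulate_quantitative(error_model_spec(n = 1000, seed = 7,
#'                                             sigma_eps = 0.5))
#' attr(s, "lambda")  # 0.8
simulate_quantitative <- function(spec) {
  stopifnot(inherits(spec, "error_model_spec"))
  out <- with_seed(spec$seed, {
    truth <- draw_truth(spec)
    ref <- truth + stats::rnorm(spec$n, 0, spec$sigma_u)
    self <- spec$a + spec$b * truth + stats::rnorm(spec$n, 0, spec$sigma_eps)
    if (spec$round_to_integer) self <- round(self)
    list(truth = truth, ref = ref, self = self)
  })
  ps <- paired_sample(variable_meta(spec$name, "quantitative",
                                    units = spec$units),
                      out$self, out$ref)
  attr(ps, "lambda") <- attenuation_lambda(spec)
  attr(ps, "truth") <- out$truth
  attr(ps, "spec") <- spec
  ps
}

#' Simulate two components with correlated reporting errors and their ratio
#'
#' Emulates ratio variables such as waist-to-hip ratio, where the reporting
#' errors of the two components are correlated (which partially cancel in
#' the ratio). Component truths are drawn independently from their specs;
#' the two reporting errors are drawn from a bivariate normal with
#' correlation `rho_eps`. Participants whose self-reported or reference
#' denominator is <= 0 are redrawn (truncation), with a warning and count.
#'
#' @param spec_numerator,spec_denominator [error_model_spec()]s for the two
#'   components. The numerator spec's seed drives all draws.
#' @param rho_eps Correlation between the two reporting errors, |rho| <= 1.
#' @return List with `numerator`, `denominator` and `ratio` (all
#'   [paired_sample()]s), the empirical `error_correlation`, and
#'   `n_resampled`.
#' @export
simulate_ratio_pair <- function(spec_numerator, spec_denominator, rho_eps) {
  stopifnot(inherits(spec_numerator, "error_model_spec"),
            inherits(spec_denominator, "error_model_spec"),
            spec_numerator$n == spec_denominator$n)
  if (abs(rho_eps) > 1) stop_domain("|rho_eps| must not exceed 1")
  n <- spec_numerator$n
  draw <- function(m) {
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    e1 <- spec_numerator$sigma_eps * z1
    e2 <- spec_denominator$sigma_eps *
      (rho_eps * z1 + sqrt(1 - rho_eps^2) * z2)
    t1 <- if (spec_numerator$truth_dist == "lognormal")
      stats::rlnorm(m, spec_numerator$mu_T, spec_numerator$sigma_T)
    else stats::rnorm(m, spec_numerator$mu_T, spec_numerator$sigma_T)
    t2 <- if (spec_denominator$truth_dist == "lognormal")
      stats::rlnorm(m, spec_denominator$mu_T, spec_denominator$sigma_T)
    else stats::rnorm(m, spec_denominator$mu_T, spec_denominator$sigma_T)
    list(self1 = spec_numerator$a + spec_numerator$b * t1 + e1,
         ref1 = t1 + stats::rnorm(m, 0, spec_numerator$sigma_u),
         self2 = spec_denominator$a + spec_denominator$b * t2 + e2,
         ref2 = t2 + stats::rnorm(m, 0, spec_denominator$sigma_u),
         e1 = e1, e2 = e2)
  }
  res <- with_seed(spec_numerator$seed, {
    d <- draw(n)
    resampled <- 0L
    for (iter in seq_len(100)) {
      bad <- which(d$self2 <= 0 | d$ref2 <= 0)
      if (!length(bad)) break
      resampled <- resampled + length(bad)
      r <- draw(length(bad))
      for (f in names(d)) d[[f]][bad] <- r[[f]]
    }
    if (any(d$self2 <= 0 | d$ref2 <= 0))
      stop_domain("denominator truncation failed: values persistently <= 0")
    c(d, list(resampled = resampled))
  })
  if (res$resampled > 0L)
    warning(res$resampled, " non-positive denominator draw(s) resampled")
  num <- paired_sample(variable_meta(spec_numerator$name, "quantitative",
                                     units = spec_numerator$units),
                       res$self1, res$ref1)
  den <- paired_sample(variable_meta(spec_denominator$name, "quantitative",
                                     units = spec_denominator$units),
                       res$self2, res$ref2)
  ratio_name <- paste0(spec_numerator$name, "_to_", spec_denominator$name)
  ratio <- paired_sample(variable_meta(ratio_name, "quantitative"),
                         res$self1 / res$self2, res$ref1 / res$ref2)
  list(numerator = num, denominator = den, ratio = ratio,
       error_correlation = stats::cor(res$e1, res$e2),
       n_resampled = res$resampled)
}

#' Simulate an ordinal self-report against a quantitative reference
#'
#' The error-prone report `a + b T + eps` is cut at the given thresholds
#' into ordered levels (level = 1 + number of thresholds at or below the
#' report), emulating category questions such as relative body size or
#' clothes size; the reference stays quantitative (`T + u`).
#'
#' @param spec An [error_model_spec()].
#' @param thresholds Strictly increasing cut points on the report scale; a
#'   single threshold yields a binary variable.
#' @return A [paired_sample()] with ordinal self-report (integer level
#'   ranks) and quantitative reference; truth attached as `attr(, "truth")`.
#' @export
simulate_ordinal <- function(spec, thresholds) {
  stopifnot(inherits(spec, "error_model_spec"))
  if (any(diff(thresholds) <= 0))
    stop_domain("thresholds must be strictly increasing")
  out <- with_seed(spec$seed, {
    truth <- draw_truth(spec)
    ref <- truth + stats::rnorm(spec$n, 0, spec$sigma_u)
    score <- spec$a + spec$b * truth + stats::rnorm(spec$n, 0, spec$sigma_eps)
    list(truth = truth, ref = ref,
         level = findInterval(score, thresholds) + 1L)
  })
  nlev <- length(thresholds) + 1L
  ps <- paired_sample(variable_meta(spec$name, "ordinal",
                                    levels = as.character(seq_len(nlev))),
                      out$level, out$ref)
  attr(ps, "truth") <- out$truth
  ps
}

#' Simulate a binary self-report with misclassification
#'
#' The reference status is Bernoulli(`p_true`); the self-report reproduces
#' it with the given sensitivity (P(report 1 | truth 1)) and specificity
#' (P(report 0 | truth 0)). The kappa expected under this model, computed
#' in closed form from the expected 2x2 table, is attached as
#' `attr(, "expected_kappa")`.
#'
#' @param p_true Prevalence in `[0, 1]`.
#' @param sensitivity,specificity Correct-report probabilities in `[0, 1]`.
#' @param n Sample size.
#' @param seed RNG seed.
#' @return A [paired_sample()] (binary, coded 1/2 for no/yes against levels
#'   `c("no", "yes")`) with attribute `expected_kappa`.
#' @export
simulate_binary <- function(p_true, sensitivity, specificity, n, seed) {
  probs <- c(p_true, sensitivity, specificity)
  if (any(probs < 0) || any(probs > 1))
    stop_domain("probabilities must lie in [0, 1]")
  out <- with_seed(seed, {
    ref <- stats::rbinom(n, 1, p_true)
    keep_p <- ifelse(ref == 1, sensitivity, specificity)
    correct <- stats::rbinom(n, 1, keep_p)
    self <- ifelse(correct == 1, ref, 1 - ref)
    list(ref = ref, self = self)
  })
  ps <- paired_sample(variable_meta("binary", "binary",
                                    levels = c("no", "yes")),
                      out$self + 1L, out$ref + 1L)
  attr(ps, "expected_kappa") <- expected_kappa(p_true, sensitivity, specificity)
  ps
}

#' Closed-form kappa for a binary misclassification model
#'
#' Evaluates Cohen's kappa on the expected 2x2 cell probabilities implied by
#' prevalence, sensitivity and specificity.
#'
#' @inheritParams simulate_binary
#' @return Expected kappa.
#' @export
expected_kappa <- function(p_true, sensitivity, specificity) {
  p11 <- p_true * sensitivity
  p10 <- p_true * (1 - sensitivity)          # truth 1, reported 0
  p01 <- (1 - p_true) * (1 - specificity)    # truth 0, reported 1
  p00 <- (1 - p_true) * specificity
  po <- p11 + p00
  p_self1 <- p11 + p01
  pe <- p_self1 * p_true + (1 - p_self1) * (1 - p_true)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Write a synthetic multi-variable cohort fixture to disk
#'
#' Generates a long-format CSV consumable by [load_paired_table()],
#' emulating a validation-study extract: several variables of mixed kinds
#' over a shared set of participants, a childhood-social-class subgroup
#' factor, and per-variable missingness that may be higher in the lower
#' social class. Byte-identical across runs for a fixed seed.
#'
#' @param config List with `n` (participants), optionally
#'   `p_low_social_class` (default 0.35), and `variables`: a named list
#'   where each entry has `kind` (`"quantitative"`, `"ordinal"`,
#'   `"binary"`), the generator parameters for that kind (for quantitative
#'   and ordinal: the [error_model_spec()] fields and, for ordinal,
#'   `thresholds`; for binary: `p_true`, `sensitivity`, `specificity`),
#'   plus optional `missing_rate` (default 0) and `missing_rate_low_class`
#'   (default `missing_rate`).
#' @param path Output CSV path.
#' @param seed Integer master seed; per-variable seeds are derived from it.
#' @return Invisibly, a list with `path`, the analysis `config` (a list of
#'   [variable_meta()] matching the fixture) and the per-variable samples.
#' @export
make_cohort_fixture <- function(config, path, seed) {
  stopifnot(is.list(config), !is.null(config$n), !is.null(config$variables))
  n <- as.integer(config$n)
  p_low <- config$p_low_social_class %||% 0.35
  social <- with_seed(seed, ifelse(stats::rbinom(n, 1, p_low) == 1,
                                   "low", "high"))
  rows <- list(); metas <- list(); samples <- list()
  vseed <- seed
  for (vn in names(config$variables)) {
    v <- config$variables[[vn]]
    vseed <- (vseed * 7 + 13) %% 2147483647
    if (v$kind == "quantitative" || v$kind == "ordinal") {
      spec <- error_model_spec(
        n = n, seed = vseed, mu_T = v$mu_T %||% 0, sigma_T = v$sigma_T %||% 1,
        a = v$a %||% 0, b = v$b %||% 1, sigma_eps = v$sigma_eps %||% 0,
        sigma_u = v$sigma_u %||% 0, name = vn, units = v$units %||% "",
        truth_dist = v$truth_dist %||% "normal")
      ps <- if (v$kind == "ordinal") simulate_ordinal(spec, v$thresholds)
            else simulate_quantitative(spec)
    } else if (v$kind == "binary") {
      ps <- simulate_binary(v$p_true, v$sensitivity, v$specificity, n, vseed)
      ps$meta$name <- vn
    } else stop_domain("unknown variable kind '", v$kind, "' for '", vn, "'")
    base_rate <- v$missing_rate %||% 0
    low_rate <- v$missing_rate_low_class %||% base_rate
    miss <- with_seed(vseed + 1, {
      stats::rbinom(n, 1, ifelse(social == "low", low_rate, base_rate)) == 1
    })
    self_chr <- format(ps$self_report, digits = 15, trim = TRUE)
    self_chr[miss] <- ""
    rows[[vn]] <- data.frame(
      id = seq_len(n), variable = vn, self_report = self_chr,
      reference = format(ps$reference, digits = 15, trim = TRUE),
      social_class = social, stringsAsFactors = FALSE)
    metas[[vn]] <- local({
      m <- ps$meta; m$name <- vn
      if (!is.null(v$category_edges)) m$category_edges <- v$category_edges
      m
    })
    samples[[vn]] <- ps
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(list(path = path, config = metas, samples = samples))
}
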