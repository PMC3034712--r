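test_that("quantitative simulation honours the error model and its seed", {
  none <- simulate_quantitative(error_model_spec(n = 100, seed = 1))
  expect_identical(none$self_report, none$reference)
  expect_equal(attr(none, "lambda"), 1)

  expect_equal(attr(simulate_quantitative(
    error_model_spec(n = 10, seed = 1, sigma_eps = 0.5)), "lambda"), 0.8)
  expect_equal(attr(simulate_quantitative(
    error_model_spec(n = 10, seed = 1, b = 0.8)), "lambda"), 1.25)

  # pure function of (spec, seed); different seeds differ
  a <- simulate_quantitative(error_model_spec(n = 50, seed = 7, sigma_eps = 1))
  b <- simulate_quantitative(error_model_spec(n = 50, seed = 7, sigma_eps = 1))
  c <- simulate_quantitative(error_model_spec(n = 50, seed = 8, sigma_eps = 1))
  expect_identical(a$self_report, b$self_report)
  expect_false(identical(a$self_report, c$self_report))

  expect_error(error_model_spec(n = 10, seed = 1, sigma_eps = -1), "sigma")
  expect_error(error_model_spec(n = 10, seed = 1, b = 0), "nonzero")
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(simulate_quantitative(error_model_spec(n = 10, seed = 99)))
  expect_identical(runif(1), before)
})

test_that("ratio pairs reproduce the configured error correlation", {
  spec_w <- error_model_spec(n = 20000, seed = 17, mu_T = 80, sigma_T = 8,
                             sigma_eps = 4, name = "waist")
  spec_h <- error_model_spec(n = 20000, seed = 17, mu_T = 100, sigma_T = 7,
                             sigma_eps = 4, name = "hip")
  indep <- simulate_ratio_pair(spec_w, spec_h, rho_eps = 0)
  expect_lt(abs(indep$error_correlation), 0.03)

  corr <- simulate_ratio_pair(spec_w, spec_h, rho_eps = 0.55)
  expect_lt(abs(corr$error_correlation - 0.55), 0.03)
  expect_equal(corr$ratio$self_report,
               corr$numerator$self_report / corr$denominator$self_report)

  # perfectly correlated equal-variance errors partially cancel in the
  # ratio: its correlation with the reference ratio beats the independent
  # case (delta-method: error variance of log-ratio collapses)
  p1 <- simulate_ratio_pair(spec_w, spec_h, rho_eps = 1)
  r_corr <- pearson_with_se(p1$ratio$self_report, p1$ratio$reference)$r
  r_ind <- pearson_with_se(indep$ratio$self_report, indep$ratio$reference)$r
  expect_gt(r_corr, r_ind)
})

test_that("ordinal simulation orders levels by truth and degrades with noise", {
  spec <- error_model_spec(n = 3000, seed = 23)
  cuts <- qnorm(c(1 / 3, 2 / 3))
  clean <- simulate_ordinal(spec, cuts)
  truth <- attr(clean, "truth")
  # no random error: level is a monotone step function of truth
  ord <- order(truth)
  expect_true(all(diff(clean$self_report[ord]) >= 0))

  rhos <- vapply(c(0, 0.5, 1, 2, 4), function(se) {
    s <- simulate_ordinal(error_model_spec(n = 3000, seed = 23,
                                           sigma_eps = se), cuts)
    ordinal_association(s)$spearman_r
  }, numeric(1))
  expect_true(all(diff(rhos) < 0))

  # one threshold gives a usable binary variable
  bin <- simulate_ordinal(spec, 0)
  bin_ref <- ifelse(bin$reference > 0, 2, 1)
  expect_equal(kappa_agreement(as.character(bin$self_report),
                               as.character(bin_ref))$kappa, 1)
})

test_that("binary misclassification matches its closed-form kappa", {
  expect_equal(expected_kappa(0.3, 1, 1), 1)
  expect_equal(expected_kappa(0.7, 0.5, 0.5), 0)
  perfect <- simulate_binary(0.4, 1, 1, 200, seed = 5)
  expect_equal(kappa_agreement(perfect)$kappa, 1)

  s <- simulate_binary(0.7, 0.95, 0.9, 50000, seed = 29)
  emp <- kappa_agreement(s)$kappa
  expect_lt(abs(emp - attr(s, "expected_kappa")), 0.02)
  expect_error(simulate_binary(1.2, 1, 1, 10, 1), "probabilities")
})

test_that("cohort fixtures are loadable, missing at the configured rate, and reproducible", {
  cfg <- list(
    n = 100,
    variables = list(
      weight = list(kind = "quantitative", mu_T = 65, sigma_T = 9,
                    a = 2, b = 0.95, sigma_eps = 2, units = "kg"),
      height = list(kind = "quantitative", mu_T = 160, sigma_T = 6,
                    sigma_eps = 1.5, units = "cm")))
  p1 <- withr::local_tempfile(fileext = ".csv")
  fix <- make_cohort_fixture(cfg, p1, seed = 11)
  lines <- readLines(p1)
  expect_length(lines, 201)  # header + 2 variables x 100 participants
  loaded <- load_paired_table(p1, fix$config)
  expect_named(loaded, c("weight", "height"))
  expect_equal(loaded$weight$n + loaded$weight$n_excluded, 100)

  # byte-identical regeneration under the same seed
  p2 <- withr::local_tempfile(fileext = ".csv")
  make_cohort_fixture(cfg, p2, seed = 11)
  expect_identical(readLines(p2), lines)

  # missingness close to its binomial expectation
  cfg$n <- 2000
  cfg$variables$weight$missing_rate <- 0.1
  p3 <- withr::local_tempfile(fileext = ".csv")
  fix3 <- make_cohort_fixture(cfg, p3, seed = 13)
  w <- load_paired_table(p3, fix3$config)$weight
  expect_lt(abs(w$n_excluded - 200), 4 * sqrt(2000 * 0.1 * 0.9))

  # subgroup-dependent missingness: low social class loses more rows
  cfg$variables$weight$missing_rate_low_class <- 0.3
  p4 <- withr::local_tempfile(fileext = ".csv")
  fix4 <- make_cohort_fixture(cfg, p4, seed = 13)
  w4 <- load_paired_table(p4, fix4$config)$weight
  miss_low <- sum(w4$excluded_subgroups$social_class == "low")
  n_low <- miss_low + sum(w4$subgroups$social_class == "low")
  miss_high <- sum(w4$excluded_subgroups$social_class == "high")
  n_high <- miss_high + sum(w4$subgroups$social_class == "high")
  expect_gt(miss_low / n_low, miss_high / n_high)
  p <- subgroup_comparison(
    c(rep("missing", miss_low), rep("present", n_low - miss_low),
      rep("missing", miss_high), rep("present", n_high - miss_high)),
    rep(c("low", "high"), c(n_low, n_high)))$p
  expect_lt(p, 0.001)
})
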