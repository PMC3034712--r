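test_that("kappa and percent agreement follow Cohen's formula", {
  # identical vectors: perfect agreement
  v <- rep(c("yes", "no"), c(6, 4))
  got <- kappa_agreement(v, v)
  expect_equal(got$kappa, 1)
  expect_equal(got$percent_agreement, 100)
  expect_equal(got$kappa_band, "excellent")

  # 2x2 table ((40,10),(10,40)): p_o 0.8, p_e 0.5, kappa 0.6
  self <- rep(c("a", "a", "b", "b"), c(40, 10, 10, 40))
  ref <- rep(c("a", "b", "a", "b"), c(40, 10, 10, 40))
  got <- kappa_agreement(self, ref)
  expect_equal(got$percent_agreement, 80)
  expect_equal(got$kappa, 0.6)
  expect_equal(got$kappa_band, "moderate")
  expect_lt(got$p_vs_chance, 0.001)

  # independent labels: chance-level kappa
  set.seed(81)
  a <- sample(c("x", "y"), 10000, replace = TRUE)
  b <- sample(c("x", "y"), 10000, replace = TRUE)
  expect_lt(abs(kappa_agreement(a, b)$kappa), 0.05)

  # both raters constant on the same label: p_e = 1, kappa undefined
  const <- kappa_agreement(rep("yes", 5), rep("yes", 5))
  expect_true(is.na(const$kappa))
  expect_equal(const$percent_agreement, 100)
})

test_that("kappa agrees with an independent implementation and is invariant", {
  set.seed(82)
  a <- sample(letters[1:3], 300, replace = TRUE, prob = c(.5, .3, .2))
  b <- ifelse(runif(300) < 0.6, a, sample(letters[1:3], 300, replace = TRUE))
  got <- kappa_agreement(a, b)
  expect_equal(got$kappa, kappa_from_table(unclass(got$table)))
  expect_equal(got$kappa,
               e1071::classAgreement(table(a, b))$kappa)
  # permutation of participants changes nothing
  perm <- sample(300)
  expect_equal(kappa_agreement(a[perm], b[perm])$kappa, got$kappa)
  # consistent relabeling leaves percent agreement unchanged
  map <- c(a = "Q", b = "R", c = "S")
  expect_equal(kappa_agreement(map[a], map[b])$percent_agreement,
               got$percent_agreement)
})

test_that("kappa bands follow the conventional cut points", {
  bands <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(k)
    recallval:::kappa_band(k), character(1))
  expect_equal(bands, c("poor", "fair", "moderate", "substantial", "excellent"))
  expect_equal(recallval:::kappa_band(0.4), "fair")   # boundary closed above
})

test_that("ordinal associations recover constructed structure", {
  # strictly separated levels: near-perfect rank correlation
  s <- paired_sample(variable_meta("size", "ordinal",
                                   levels = c("lo", "mid", "hi")),
                     rep(1:3, each = 10),
                     c(rnorm(10, 0, .1), rnorm(10, 5, .1), rnorm(10, 10, .1)))
  got <- ordinal_association(s)
  expect_gt(got$spearman_r, 0.9)
  expect_lt(got$trend_p, 1e-6)
  expect_equal(got$levels$n, rep(10, 3))

  # independence: rank correlation near zero
  set.seed(91)
  s0 <- paired_sample(variable_meta("size", "ordinal"),
                      sample(rep(1:4, length.out = 5000)), rnorm(5000))
  expect_lt(abs(ordinal_association(s0)$spearman_r), 0.05)

  expect_error(ordinal_association(
    paired_sample(variable_meta("size", "ordinal"), rep(1, 5), rnorm(5))),
    "single occupied level")
})

test_that("ordinal per-level means and midrank Spearman match hand arithmetic", {
  s <- paired_sample(variable_meta("size", "ordinal"),
                     c(1, 1, 2, 2, 3, 3), c(1, 2, 3, 4, 5, 6))
  got <- ordinal_association(s)
  expect_equal(got$levels$mean_ref, c(1.5, 3.5, 5.5))
  expect_equal(got$spearman_r,
               spearman_midrank(c(1, 1, 2, 2, 3, 3), c(1, 2, 3, 4, 5, 6)))
  # invariance to strictly monotone relabeling of the levels
  relab <- paired_sample(variable_meta("size", "ordinal"),
                         c(10, 10, 20, 20, 35, 35), c(1, 2, 3, 4, 5, 6))
  expect_equal(ordinal_association(relab)$spearman_r, got$spearman_r)
})

test_that("2x2 subgroup comparisons are exactly Fisher by enumeration", {
  tab <- matrix(c(5, 0, 0, 5), 2)
  got <- subgroup_comparison(rep(c("m", "m", "f", "f"), c(5, 0, 0, 5)),
                             rep(c("lo", "hi", "lo", "hi"), c(5, 0, 0, 5)))
  expect_equal(got$p, fisher_2x2_enumeration(tab))
  expect_equal(got$method, "fisher_exact_2x2")

  # identical rows: no association, p = 1
  out <- rep(c("y", "n"), c(6, 6))
  fac <- rep(c("a", "b"), 6)
  expect_equal(subgroup_comparison(out, fac)$p, 1)

  # every 2x2 table with n <= 20 matches the enumeration oracle
  for (a in 0:4) for (b in 0:4) for (d in 0:4) for (e in 0:4) {
    m <- matrix(c(a, b, d, e), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    o <- rep(c("y", "y", "n", "n"), c(a, d, b, e))
    f <- rep(c("p", "q", "p", "q"), c(a, d, b, e))
    expect_equal(subgroup_comparison(o, f)$p, fisher_2x2_enumeration(m),
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo subgroup p agrees with full enumeration on r x 2", {
  tab <- matrix(c(6, 1, 2, 1, 4, 5), nrow = 3, byrow = TRUE)
  o <- rep(rep(c("g1", "g2", "g3"), 2), times = c(tab[, 1], tab[, 2]))
  f <- rep(rep(c("A", "B"), each = 3), times = c(tab[, 1], tab[, 2]))
  got <- subgroup_comparison(o, f, n_perm = 20000, seed = 5)
  expect_equal(got$method, "monte_carlo_fixed_margins")
  exact <- exact_rx2_enumeration(tab)
  expect_lt(abs(got$p - exact), 3 * got$mc_se)
  # deterministic under a fixed seed
  expect_identical(subgroup_comparison(o, f, n_perm = 20000, seed = 5)$p,
                   got$p)
})
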