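# Independent oracles, deliberately written from first principles so they
# share no code with the implementation under test.

# Quantitative paired sample without going through the simulators.
make_sample <- function(self, ref, kind = "quantitative", ...) {
  paired_sample(variable_meta("v", kind, ...), self, ref)
}

# ICC(1,1) by explicit one-way ANOVA sums of squares on the long layout:
# 2n observations, participant as the grouping factor.
icc_brute_force <- function(x, y) {
  n <- length(x)
  vals <- c(x, y)
  subj <- rep(seq_len(n), 2)
  grand <- mean(vals)
  ss_total <- sum((vals - grand)^2)
  subj_means <- (x + y) / 2
  ss_between <- sum(2 * (subj_means - grand)^2)
  ss_within <- ss_total - ss_between
  msb <- ss_between / (n - 1)
  msw <- ss_within / n          # df = n (k - 1), k = 2
  (msb - msw) / (msb + msw)
}

# Two-sided Fisher exact p for a 2x2 table by full enumeration over all
# tables with the observed margins, summing hypergeometric probabilities
# no larger than the observed one.
fisher_2x2_enumeration <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact conditional p for an r x 2 table by enumerating all tables with the
# observed margins (first column entries vary freely within row totals).
exact_rx2_enumeration <- function(tab) {
  stopifnot(ncol(tab) == 2)
  rows <- rowSums(tab); c1 <- sum(tab[, 1])
  logp <- function(first_col) {
    m <- cbind(first_col, rows - first_col)
    sum(lgamma(rows + 1)) + sum(lgamma(colSums(m) + 1)) -
      lgamma(sum(m) + 1) - sum(lgamma(m + 1))
  }
  grids <- lapply(rows, function(r) 0:r)
  combos <- as.matrix(expand.grid(grids))
  combos <- combos[rowSums(combos) == c1, , drop = FALSE]
  lps <- apply(combos, 1, logp)
  obs <- logp(tab[, 1])
  sum(exp(lps[lps <= obs + 1e-7])) / sum(exp(lps))
}

# Cohen's kappa straight from a contingency matrix.
kappa_from_table <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

# Spearman correlation via the midrank definition (Pearson on midranks).
spearman_midrank <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
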