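---
title: "Measuring and correcting reporting error in validation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and correcting reporting error in validation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallval)
```

## The measurement model

A validation study observes, for each participant, a self-reported value
and a reference measurement of the same quantity. `recallval` analyses
such data under (and its generator simulates from) the linear differential
error model

$$X = a + b\,T + \varepsilon, \qquad R = T + u,$$

where $T$ is the unobserved true value with mean $\mu_T$ and SD
$\sigma_T$, $X$ the self-report, $R$ the reference,
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$ the random reporting error,
and $u \sim N(0, \sigma_u^2)$ an optional reference-side error (an
"alloyed gold standard": the reference is treated as truth but may carry a
small random error uncorrelated with everything else). The intercept $a$
and slope $b$ encode systematic error: $b < 1$ (or $a < 0$) reproduces the
familiar pattern of under-reporting that grows with the true value, as
seen for self-reported weight. The model is linear in $T$ because the
empirical signatures of differential reporting error — monotone mean error
across reference quintiles, approximately linear category-mean plots — are
consistent with linearity; threshold effects and digit preference are not
modelled (an optional rounding switch exists but no statistical claims are
attached to it).

## Agreement statistics and what each one sees

For a quantitative variable the package reports:

* **Mean difference and paired *t*-test** (`mean_difference_test`):
  detects average over- or under-reporting. Two-sided throughout. When the
  difference vector has zero variance, the p-value is the analytic limit
  (0 for a nonzero constant shift, 1 for perfect agreement) and the result
  is flagged degenerate rather than erroring.
* **95% limits of agreement** (`limits_of_agreement`):
  $\bar d \pm 1.96\, s_d$ for $d = X - R$, the typical range of individual
  reporting errors. The multiplier is fixed at 1.96 (no small-sample *t*
  correction), following the standard Bland–Altman definition. Because
  attenuation of associations depends on the error SD relative to the SD
  of true values, the bounds are also reported divided by the reference
  SD — specifically the reference-only SD, not a pooled one, since the
  reference plays the role of truth. The bounds are not centred at zero:
  a mean bias shifts both, which is why scaled limits can be asymmetric.
* **ICC(1,1)** (`icc_1_1`): the one-way random-effects intraclass
  correlation treating the two sources as $k = 2$ single ratings,
  $(MS_B - MS_W)/(MS_B + MS_W)$. Unlike the Pearson correlation it is
  reduced by systematic as well as random disagreement, so the gap between
  $r$ and the ICC isolates systematic error. Its SE uses the large-sample
  form $\sqrt{2(1-\rho)^2(1+\rho)^2 / (2(n-1))} = (1-\rho^2)/\sqrt{n-1}$.
* **Pearson $r$ with** $se = \sqrt{(1-r^2)/(n-2)}$: the SE formula is the
  standard large-sample expression; other choices (Fisher-z) differ at
  the third decimal for the sample sizes this package targets.
* **Quintile error profile** (`quintile_error_profile`): mean and SD of
  $d$ within strata cut at the empirical 20/40/60/80 percentiles of the
  reference, with a one-way ANOVA for equality of stratum mean errors.
  Ties are assigned to the lower stratum (right-closed cuts), so strongly
  tied variables produce visibly unequal stratum sizes — expected
  behaviour, not an error. Strata with fewer than 2 observations are
  flagged and excluded from the ANOVA; error-free data make the ANOVA
  degenerate and it is reported as such rather than as a p-value.

Ordinal self-reports (clothes sizes, relative body size) are scored by
their integer group ranks (1 = lowest) and related to the quantitative
reference by the Spearman correlation (midranks for ties — the tie rule is
a package choice) and a linear-trend p-value from the least-squares
regression of the reference on the rank score, equivalent to the
one-degree-of-freedom linear contrast. Binary variables get percent
agreement and Cohen's $\kappa$ with the conventional bands (≤0.2 poor,
then fair/moderate/substantial at steps of 0.2, >0.8 excellent); the test
against chance agreement is the large-sample $z$-test of $\kappa = 0$ with
the Fleiss null SE, a choice the package makes explicit since several
tests exist. Subgroup comparisons (e.g. of missingness by childhood social
class) use Fisher's exact test for 2×2 tables and a seeded Monte-Carlo
fixed-margins approximation (≥10 000 tables, with its Monte-Carlo SE) for
larger ones.

## Regression dilution ratios

The headline statistic is deliberately non-parametric. Participants are
grouped by pre-specified categories of the *self-reported* value;
category means of both members are computed, and

$$\widehat{RDR} = \frac{\max_c \bar R_c - \min_c \bar R_c}
                       {\max_c \bar X_c - \min_c \bar X_c}.$$

Under the linear model above, the conditional mean of $R$ given $X$ has
slope $\lambda = b\sigma_T^2 / (b^2\sigma_T^2 + \sigma_\varepsilon^2)$,
and the range-of-means estimator is consistent for $\lambda$ — regardless
of the offset $a$ and of reference-side error $\sigma_u$. A log relative
risk fitted to self-reported exposure is attenuated by exactly this
factor, so `correct_relative_risk(rr, rdr)` = $\exp(\log rr / RDR)$
de-attenuates it; `attenuation_percent` is $100(1 - RDR)$. Note
$\lambda > 1$ is possible: with $b < 1$ and small random error,
compressive systematic error *inflates* associations
($b = 0.8, \sigma_\varepsilon = 0 \Rightarrow \lambda = 1.25$), the
mechanism by which differential under-reporting of weight can cancel
random-error attenuation. Lost power is a separate matter: the squared
self-report–reference correlation gives the effective sample size as a
fraction of the actual one, and no RDR correction recovers it.

Design choices that were genuinely open:

* **Categories.** Edges are config-supplied per variable (they are part
  of the analysis plan); when none are given, empirical quintile breaks of
  the self-report are used. Edges form a full breaks vector; categories
  are $[e_i, e_{i+1})$ with the last closed, and outer edges may be
  infinite. A slope-based estimator (`rdr_slope`) is provided purely as a
  cross-check; it is *not* the headline statistic, because the range form
  stays meaningful under non-normal category structure.
* **Bootstrap.** Percentile intervals from the 2.5th/97.5th percentiles
  of the RDR over `n_boot = 2000` (default) resamples. The resampling
  unit is the participant pair, preserving the within-pair error
  structure. Category edges are resolved once on the original sample and
  held fixed across replicates. Replicates in which an originally
  occupied category empties, or the self-report mean range collapses, are
  discarded and counted (sparse categories routinely empty under
  resampling; discarding is preferable to failing), and more than 50%
  discarded aborts with a diagnostic. With a fixed seed the interval is
  bit-reproducible, and the seed is recorded in the result and manifest.
* **Descriptive bands.** `classify_rdr` labels RDRs below 0.66
  "substantial" attenuation, 0.66–0.86 "slight-to-moderate", above 0.86
  "little-or-none". These are descriptive conventions for reporting, not
  inferential claims, and the boundaries are override-able.

## Data preparation

Input is long format (one row per participant × variable), so variables
with different complete-case counts coexist cleanly; `wide_to_long`
converts the common wide layout. Missingness is handled per variable pair
(complete-case), never listwise, and excluded counts (with their subgroup
labels) are retained for missingness analyses. Blank cells and
"don't know" tokens are both treated as missing — the two cannot be
distinguished downstream and no imputation is attempted. Unit conversions
use the international exact factors (1 in = 2.54 cm,
1 lb = 0.45359237 kg); months are divided by 12 without rounding. Ages
recorded only in whole years understate the exact age by six months on
average, so `adjust_integer_age` adds 0.5 — applied only to variables
flagged `integer_years` in the config, never automatically.

## What the synthetic generator does and does not emulate

`simulate_quantitative`, `simulate_ratio_pair`, `simulate_ordinal`,
`simulate_binary` and `make_cohort_fixture` produce seeded, bit-reproducible
data with: linear differential error; correlated reporting errors between
two components of a ratio (drawn bivariate-normal with correlation
$\rho_\varepsilon$; the two *truths* are drawn independently, since only
the error correlation is pinned by the phenomenon being emulated — real
waist and hip are themselves correlated, so simulated ratio *levels* are
more dispersed than real ones); ordinal levels by thresholding the
error-prone report; and binary misclassification parameterised by
prevalence, sensitivity and specificity, with the expected $\kappa$
attached in closed form. Truths are normal by default (the variables this
design targets are roughly symmetric) with a log-normal option for skewed
ones. Not modelled: digit preference and heaping, within-person drift over
follow-up, non-linear reporting error. Passing tests therefore demonstrate
correctness of the statistics under the stated error model, not robustness
to every feature of real questionnaire data.

```{r example}
spec <- error_model_spec(n = 2000, seed = 17, mu_T = 13.1, sigma_T = 1.4,
                         sigma_eps = 1, name = "age_menarche", units = "years")
s <- simulate_quantitative(spec)
summarize_agreement(s)
rdr_bootstrap_ci(s, n_boot = 2000, seed = 17)
attr(s, "lambda")  # analytic attenuation for this error model
```

## Numerical choices, degenerate inputs, problem sizes

Quantile-based edges use R's default (type 7) empirical quantiles;
duplicate quantile edges (heavy ties) are collapsed with a warning.
Constant vectors make the Pearson correlation and the ICC undefined and
raise errors saying so; $p_e = 1$ leaves $\kappa$ undefined while percent
agreement is still reported; a record is still produced at $n = 2$ but
flagged unreliable (limits of agreement and the ICC need $n \ge 3$).
Band boundaries ($\kappa$ bands, RDR bands) are compared with a $10^{-9}$
tolerance so that exactly-boundary values land in the conventional band
despite floating-point round-off.

The test suite exercises the estimators at the sizes where their
asymptotics are informative but runs stay comfortable on one CPU:
$n = 50\,000$ single-shot recovery of $\lambda \in \{0.5, 0.8, 1, 1.25\}$
(tolerance 0.05), a 200-replicate coverage study of the bootstrap interval
at $n = 500$ with 500 resamples each, and $n = 20\,000$ for the
correlated-error ratio check (tolerance 0.03 on the configured 0.55).

## Limitations

The RDR correction applies to linear (log-linear) univariate
associations; it is not suitable for non-linear dose–response shapes or
for multivariable regression-calibration with covariates, which are out
of scope. The reference is assumed at worst an alloyed gold standard with
errors uncorrelated with the quantities of interest; correlated
reference-side error biases the RDR itself. Bands and classifications are
reporting conveniences, not tests.
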