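Package: recallval
Title: Agreement Statistics and Regression Dilution Ratios for
    Validation Studies of Self-Reported Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies random and systematic reporting error in paired
    self-reported versus reference measurements from validation studies,
    and estimates the consequences for disease-exposure associations.
    Implements Bland-Altman limits of agreement (raw and scaled to the
    reference standard deviation), the one-way random-effects intraclass
    correlation ICC(1,1), paired t-tests, quintile profiles of over- and
    under-reporting, Cohen's kappa with agreement bands, Spearman and
    linear-trend analysis for ordinal body-size variables, and
    non-parametric regression dilution ratios (the ratio of the range of
    reference category means to the range of self-report category means)
    with percentile-bootstrap confidence intervals, relative-risk
    correction and effective-sample-size accounting. A seeded synthetic
    cohort generator with a linear differential error model, correlated
    component errors, ordinal thresholding and binary misclassification
    supports testing and power studies without access to individual-level
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
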