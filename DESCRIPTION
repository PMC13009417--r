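Package: trialemu
Title: Target Trial Emulation of Antihypertensive Initiation and Weight
    Change with Inverse-Probability-Weighted Marginal Structural Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Emulates a pragmatic trial of seven first-line antihypertensive
    monotherapies (lisinopril reference) on weight change using EHR-shaped
    prescription, vitals, encounter and condition tables. Provides a
    synthetic EHR generator with known causal ground truth (confounded
    assignment, covariate-driven discontinuation, informative weight
    measurement, around half of days-supply fields missing), new-user
    cohort construction with a documented exclusion cascade,
    medication-on-hand reconstruction with nearest-fill imputation and a
    one-month grace period, pooled logistic inverse-probability weights for
    outcome measurement and adherence censoring (truncated at a percentile
    cap), a weighted repeated-outcomes marginal structural model with a
    restricted cubic spline in time and treatment-by-time interactions,
    g-computation standardization, contrasts versus a reference arm, risks
    of gaining at least 5% of baseline weight, and patient-level bootstrap
    confidence intervals, with subgroup and sensitivity re-runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    Rcpp,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
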