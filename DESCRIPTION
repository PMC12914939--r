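Package: cacemeta
Title: Comparing Treatment-Policy and Efficacy Estimands in IPD Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the empirical comparison of intention-to-treat (ITT),
    per-protocol (PP) and complier average causal effect (CACE) estimands in
    randomised trials with one-sided non-adherence. Provides per-trial
    estimators (baseline-adjusted linear and logistic models, two-stage
    least-squares and principal-stratification maximum likelihood for the
    CACE), two-stage random-effects individual-participant-data meta-analysis
    with REML heterogeneity estimation, correlated-difference pooling of
    method contrasts (differences in standardised mean differences and ratios
    of odds ratios), one-stage mixed-model analyses, heterogeneity and
    small-study diagnostics, and a synthetic multi-trial generator with known
    true estimands for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    metafor,
    lme4,
    sandwich,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
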