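Package: valuesetdrift
Title: Demographic Sensitivity of EQ-5D-3L Value Sets from Time Trade-Off Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits Bayesian heteroskedastic Tobit models to EQ-5D-3L time
    trade-off (TTO) valuation data with sex- and age-group-specific
    multiplicative preference-scale parameters, then derives demographically
    weighted value sets under two population compositions and the posterior
    distribution of their difference.  Includes respondent-level quality
    filters (minimum task counts, positively sloped misery-index responders),
    a Metropolis-within-Gibbs sampler with antithetic proposals and slice
    updates for mean-one constrained scale parameters, convergence
    diagnostics, a synthetic TTO-study generator for validation, and an
    end-to-end pipeline producing value-set comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
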