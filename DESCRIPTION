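Package: erspc
Title: Posterior Predictive Checks for Extreme Response Style in Polytomous Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects extreme response style (ERS) in Likert-type questionnaire
    data with Bayesian posterior predictive checks on the generalized partial
    credit model (GPCM). Provides MCMC estimation of the (multidimensional)
    GPCM with rank-normalized split-Rhat and bulk/tail effective-sample-size
    diagnostics, four tailored posterior predictive p values (person- and
    group-level checks based on extreme-response proportions and a squared
    observed-minus-expected discrepancy), an IRTree-based synthetic-data
    generator with a discrete ERS trait, and a simulation harness that
    measures false- and true-positive rates of the checks across study
    conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
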