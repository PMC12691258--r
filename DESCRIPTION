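Package: ubd
Title: Risk Stratification by Repeated Imperfect Diagnostic Tests
Version: 1.0.0
Authors@R:
    person("UBD", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Updated Bayesian Deduction (UBD) splits a cohort by the outcome of
    an imperfect diagnostic test, assigns each subcohort its Bayes-updated
    prevalence, and iterates, so that repeated cheap tests (such as faecal
    immunochemical tests for colorectal cancer) stratify disease risk and
    prioritise scarce confirmatory procedures (colonoscopies). Provides the
    single-test Bayesian machinery, the recursive expected-count cohort tree
    with order-invariant aggregation by outcome profile, posterior
    trajectories, action-tier triage with waiting-list metrics, protocol cost
    reporting, calibration of prevalence/sensitivity/specificity from
    confusion tables or stratified indicators, and a patient-level Monte
    Carlo oracle for the analytic expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
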