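Package: wtmsm
Title: Multistate Markov Models for Longitudinal Weight Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying longitudinal weight change in primary-care
    populations with panel-observed multistate Markov models. Weight status is
    categorised into five states relative to baseline weight (>=10% loss, 5-10%
    loss, within +/-5%, 5-10% gain, >=10% gain) and patients move between
    adjacent states at transition intensities that depend multiplicatively on
    demographics and on time-varying weight-management-treatment exposures
    (nutrition counseling, meal-replacement programs, anti-obesity medication,
    bariatric surgery). The package provides a synthetic electronic-health-record
    generator with known ground truth, cohort construction and exposure coding,
    cross-sectional generalized-estimating-equation comparisons with average
    marginal effects, propensity-score stratified optimal 1:1 matching, maximum
    likelihood estimation of the multistate model from interval-censored panel
    data via matrix-exponential transition probabilities, one-year state
    probability prediction with simulation-based confidence intervals, and
    population counterfactual summaries (average marginal effects, attributable
    fractions, fold-increase utilization scenarios and the loss-versus-gain
    tipping point).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
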