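Package: resilmark
Title: Mobile-Sensing Indicators of Stress-Resilience
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and predicting wearable-sensing and
    ecological momentary assessment (EMA) indicators of stress-resilience in
    cohorts under prolonged occupational stress, modelled on year-long
    medical-internship studies. Builds per-participant summary indicators
    (means, standard deviations, Pearson skew, Cohen's d_s, data counts) from
    hourly step, sleep, heart-rate and mood streams; cleans raw streams via
    mood interpolation, missingness rules and isolation-forest outlier
    filtering; classifies depression-symptom (PHQ-9) trajectories with
    quadratic growth mixture models fitted by EM; screens indicators against
    the resilient class with cluster-robust logistic generalized estimating
    equations; learns the baseline-to-internship feature mapping with
    multitask conditional GANs and baseline regressors; and evaluates
    predicted indicators with skipped (robust) correlations and signed-rank
    comparisons against a mean-assignment baseline. A synthetic cohort
    generator with planted trajectory classes, behaviour-shift clusters and
    indicator couplings makes the full pipeline testable without access to
    raw study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
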