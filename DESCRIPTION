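Package: distcue
Title: Distributional-Cue Models of Expectation and Cued Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people form expectations from
    distributional cues (sets of ten ratings on a 0-100 visual analogue
    scale with controlled mean, variance and skewness) and how those
    expectations shape subsequent pain and visual perception. Provides
    constrained generation of cue distributions and factorial trial
    designs, a power/logistic cue-value weighting model of expectation
    generation with per-participant bounded least-squares fitting and
    group-level nonparametric tests, five nested observer models of cued
    perception with prediction-error driven weight updating and nested
    F-test / AIC model comparison, a synthetic-cohort simulator for
    parameter-recovery and model-identification studies, and a pipeline
    that exports mixed-model-ready regressor codings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
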