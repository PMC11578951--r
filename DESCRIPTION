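Package: fcontrol
Title: Functional Brain Controllability Analysis for Deep Brain
    Stimulation Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes average and modal controllability of functional
    brain networks under a discrete-time linear network-control model,
    forms medication-induced delta-controllability profiles, screens
    regions whose controllability is both disease-aberrant and
    medication-responsive, relates delta controllability to percent
    motor improvement after deep brain stimulation, and predicts
    improvement with epsilon-support-vector regression under
    leave-one-subject-out cross-validation. Includes ROI time-series
    cleaning (band-pass filtering, nuisance regression with an expanded
    24-parameter motion model, framewise-displacement scrubbing,
    Pearson functional connectivity) and a synthetic-cohort generator
    with planted, analytically checkable effects for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
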