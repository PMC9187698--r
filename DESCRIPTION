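Package: icpcast
Title: Probabilistic Forecasting of Elevated Intracranial Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forecasts dangerously elevated intracranial pressure (ICP >= 20
    mmHg) over six 10-minute horizons from the preceding hour of a patient's
    minute-resolution ICP recording.  The predictor is a dynamic naive Bayes
    classifier over third-quartile-discretized 10-minute interval levels,
    fitted by (optionally smoothed) maximum likelihood, with an
    alpha-weighted decision rule that trades specificity for sensitivity to
    compensate for the strong class imbalance of ICU pressure data.  Includes
    patient-level evaluation designs (random 80/20 interval splits with
    nonparametric bootstrap confidence intervals, and leave-one-patient-out
    cross-validation with proportion-weighted summaries), a two-state
    Markov-regime synthetic cohort generator so the whole pipeline is
    testable without patient data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
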