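Package: gazestate
Title: Gaze-Event Detection, Eye-Tracking Metrics and Cognitive-State
    Classification for VR Learning Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing head-mounted-display eye-tracking data
    from virtual-reality learning sessions. Implements velocity-threshold
    (I-VT) fixation and saccade detection from 3D gaze-direction streams,
    ray-cast attribution of gaze events to areas of interest with
    cumulative eye-tracking metric accumulation, a calibrated synthetic
    generator of gaze streams, per-session metrics and questionnaire
    scores for a 26-participant three-state within-subject design, the
    repeated-measures statistical battery (RM-ANOVA with Greenhouse-
    Geisser correction, Bonferroni post hocs with Cohen's d, Pearson
    correlations), and subject-independent cognitive-state classification
    with a from-scratch LSTM plus tree-ensemble baselines under
    leave-one-subject-out cross-validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    jsonlite,
    rlang,
    readr,
    tibble,
    dplyr,
    tidyr,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
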