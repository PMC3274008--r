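Package: emgfatigue
Title: Detection and Prediction of Localised Muscle Fatigue from Surface
    EMG and Elbow Kinematics
Version: 1.0.0
Authors@R:
    person("emgfatigue", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for autonomous detection and prediction of localised
    muscle fatigue during isometric contractions.  Implements zero-phase
    Butterworth preprocessing of surface electromyography (sEMG), the
    one-dimensional spectrogram composite feature (Welch total band power
    unified by subtraction with the instantaneous median frequency), a
    fuzzy rule-based labeller driven by elbow-angle kinematics, a Fisher
    linear discriminant separating Non-Fatigue from Transition-to-Fatigue,
    and a timer-based predictor of the clock time of fatigue onset.  A
    seeded synthetic trial generator emulates fatiguing biceps-curl trials
    (declining median frequency, rising power, elbow-angle drift and
    oscillation) so the full pipeline is testable without recordings.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
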