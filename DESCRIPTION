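Package: seizecast
Title: Short-Horizon Neonatal Seizure Forecasting from Quantitative EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for short-horizon neonatal seizure
    prediction from multichannel scalp EEG. Provides a synthetic
    neonatal-EEG cohort generator with a tunable planted preictal
    signature, EDF input/output and bipolar montage derivation,
    band-pass preprocessing and resampling, epoch-level state labeling
    (ictal/preictal/interictal with right-censor exclusion), quantitative
    EEG feature extraction (asymmetry indices of statistical moments,
    band powers, recurrence quantification analysis), a convolutional
    LSTM sequence classifier trained under subject-stratified nested
    cross-validation, an SPH/SOP seizure alarm system with time-point
    sensitivity, corrected time-in-warning, false detection rate and
    threshold-sweep metrics, and probability calibration assessment
    (reliability tables, expected calibration error, Brier skill score).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
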