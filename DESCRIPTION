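Package: papwave
Title: Noninvasive Pulmonary Artery Pressure Waveform Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the pulmonary artery pressure (PAP) waveform
    from noninvasive bedside signals (ECG, photoplethysmogram, respiration).
    Provides a physiologically coupled six-channel hemodynamic waveform
    simulator with known per-beat ground truth, zero-phase band-pass
    preprocessing and sliding-window segmentation with patient-level dataset
    splits, wavelet scattering features and an invertible 7-band maximal
    overlap discrete wavelet transform (MODWT, sym4) target representation,
    a registry of eleven regression models including a 1-D residual
    convolutional network, ECG-constrained per-beat systolic/diastolic
    pressure extraction, and waveform/beat agreement metrics with bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    glmnet,
    e1071,
    kernlab,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
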