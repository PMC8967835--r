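Package: ppgaf
Title: Atrial Fibrillation Detection from Wrist Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects atrial fibrillation from wrist-worn photoplethysmogram
    (PPG) recordings by pulse-to-pulse interval (PPI) analysis. Provides a
    synthetic PPG and triaxial accelerometer simulator with ground-truth
    rhythm labels (sinus rhythm, atrial fibrillation, ventricular bigeminy,
    premature atrial complexes), accelerometer-based motion-artifact gating
    and signal-quality rules, smoothing-spline baseline removal and
    denoising, peak detection and N-beat segmentation, a panel of
    heart-rate-robust interval and pulse-morphology features (SD, RMSSD,
    Shannon entropy, rolling three-segment statistics, autocorrelation and
    unimodality features), support-vector-machine and random-forest
    classifiers under patient-wise cross-validation, and ROC/AUC evaluation
    with DeLong confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    e1071,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
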