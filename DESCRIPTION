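Package: ahretriage
Title: Classification and Triage of Atrial High-Rate Episodes from
    Intracardiac Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for classifying atrial high-rate episodes
    (AHREs) recorded by remotely monitored pacemakers and defibrillators
    into atrial tachycardia/fibrillation (AT/AF), noise, and far-field
    oversensing (FFO). Provides a seeded multi-center synthetic
    electrogram cohort generator, training-time signal augmentation, a
    self-contained 1D residual network classifier trained with categorical
    focal loss and class-weighted F2 checkpoint selection, center-level
    fourfold cross-validation with patient-level splits, a soft-voting
    ensemble with probability-threshold triage, patient-level bootstrap
    evaluation, and Grad-CAM++ saliency maps for one-dimensional signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    arrow,
    ggplot2,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
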