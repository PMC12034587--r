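Package: plaqrisk
Title: Pathological Risk Scoring and Cardiovascular Event Prediction from
    Carotid Plaque Histology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-step prediction of cardiovascular events within one year
    after carotid endarterectomy. Whole-slide histology images of resected
    carotid plaques are segmented (HSV saturation, median filter, Otsu
    binarization, morphological closing), tiled into 256x256 patches, and
    scored by a reconstruction-based anomaly detector (convolutional
    autoencoder, with an optional f-AnoGAN izif variant) trained on
    event-free patients only. Per-patch anomaly scores are averaged into a
    per-patient pathological risk score, visualized as anomaly heat maps,
    and combined with 18 clinical variables in a gradient-boosted
    classifier evaluated by repeated stratified 7:3 splits with five-fold
    cross-validated grid search, Youden-index thresholding, and 95%
    confidence intervals. A seeded synthetic-slide and synthetic-cohort
    generator provides ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    png,
    xgboost,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
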