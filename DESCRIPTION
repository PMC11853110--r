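Package: gaitpress
Title: Plantar-Pressure Gait Recognition with Open-Set Rejection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for person identification from plantar pressure recorded
    on a piezoresistive floor mat. Includes a synthetic pressure-mat walk
    simulator (per-subject footprint templates, alternating left/right
    steps, stance/swing phasing, optional carried load), preprocessing of
    raw frame streams into per-gait-cycle 32x32 average bilateral pressure
    maps (anomaly replacement, ROI segmentation, gait-cycle timing, flip
    augmentation), a small convolutional classifier for closed-set
    identification, an autoencoder embedding (256 to 64 dimensions) with
    cosine-similarity thresholding for open-set recognition of
    unauthorized walkers, and a biometric evaluation suite (FAR, FRR, EER,
    ROC/AUC, precision/recall/F1, misclassification attribution).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
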