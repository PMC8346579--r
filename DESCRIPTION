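Package: airwaynet
Title: Airway Tree Segmentation from Thoracic CT with a Memory-Efficient 3D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for segmenting the bronchial tree from
    volumetric chest CT with a 3D U-Net that uses non-padded (valid)
    convolutions in its first resolution levels and zero-padding thereafter,
    trained on large random patches with a lung-masked soft Dice loss.
    Includes sliding-window overlap-averaged inference, rule-based
    post-processing into a single connected airway tree, skeleton-based
    evaluation metrics (tree length detected, centerline leakage, false
    positive rate, Dice, total tree length), simplified region-growing lung
    and central-airway segmentation, and a synthetic branching-tube CT
    phantom generator with exact ground truth so the whole pipeline can be
    trained and validated on a desktop CPU without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
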