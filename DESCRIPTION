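Package: vasccalc
Title: Automated Vascular Calcification Scoring from CT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segmentation-based measurement of arterial calcification in
    contrast-enhanced CT volumes. Provides a synthetic CT-angiography
    phantom generator with analytically known vessel masks and calcium
    volumes, a U-Net style encoder-decoder segmentation network trained
    with a combined binary cross-entropy and Jaccard loss under
    patient-level k-fold cross-validation, intensity-threshold calcium
    scoring with volumetric conversion, the standard overlap and
    error metrics (Dice, IOU, MAPE, APE, R-squared), and a reproducible
    end-to-end pipeline with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    EBImage,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
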