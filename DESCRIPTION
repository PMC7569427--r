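Package: wanet
Title: Wide-Activation Residual Networks for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pixel-level segmentation of blood vessels in fundus photographs
    with a wide-activation residual encoder-decoder: residual blocks whose
    channels are expanded before the activation while the identity path is
    slimmed to preserve parameter complexity, an atrous spatial pyramid
    bottleneck, weight normalization, and a combined cross-entropy plus Dice
    objective. Includes fundus preprocessing (grayscale, standardization,
    CLAHE, gamma correction), overlapping-patch extraction with exact
    overlap-average reconstruction, Adam training, patch-based full-image
    inference, segmentation metrics with ROC/AUC, ablation variants of the
    architecture, and a seeded synthetic fundus generator so the complete
    pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
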