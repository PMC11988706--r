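Package: carunet
Title: Lightweight Convolutional Attention Residual U-Net for Lung-Field Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates a lightweight residual U-Net with
    convolutional block attention (CBAM), atrous spatial pyramid pooling (ASPP)
    and attention-gated skip connections for binary lung-field segmentation of
    chest radiographs. Ships a deterministic synthetic phantom generator, a
    reproducible preprocessing/splitting/augmentation pipeline, Dice/BCE/Focal
    compound losses, segmentation metrics, a seeded trainer with k-fold
    cross-validation and ablation grids, Mann-Whitney U comparisons, analytic
    parameter counting with width calibration to fixed parameter budgets, and a
    command-line interface. The network core (tensor operators, reverse-mode
    differentiation, optimizers) is implemented in R with C++ kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
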