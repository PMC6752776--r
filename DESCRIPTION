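Package: fundusAdapt
Title: Self-Adaptive Training and Laterality Detection for Color Fundus
    Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting eye laterality (left versus right eye) from
    color fundus photographs with a convolutional classifier trained under a
    monitor-driven self-adaptive strategy. Provides fundus image size
    normalisation (dark-border cropping, square cropping, rescaling,
    circular masking of the overexposed rim), four enhancement
    methods (none, CLAHE on the CIELAB luminance, local-space-average-color
    removal, gray transformation), a compact CNN engine with an Inception-V3
    style and a desk-scale backbone, a plateau-triggered learning-rate
    controller with a gated best-model pool, class activation maps for the
    GAP-headed classifier, ROC/AUC evaluation with Wilson and DeLong
    confidence intervals, and a synthetic fundus photograph generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
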