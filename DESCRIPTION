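Package: pdhand
Title: Parkinson's Disease Detection from Handwriting Drawings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting Parkinson's disease from offline
    handwriting drawings (Archimedean spirals and meanders). Implements a
    modified Wiener filter for pre-processing, a modified pyramid histogram
    of oriented gradients (PHOG) descriptor with entropy-augmented
    gradients, contour shape features, optional deep-feature backbones, and
    a hybrid classifier combining a GhostNet branch with an improved
    LinkNet branch (Gabor/multi-kernel MDSCM module and weighted-average-
    pooling batch normalisation), fused by mean scoring. Ships a parametric
    spiral/meander tremor simulator so the full pipeline is testable
    without external data, plus dataset manifest utilities, augmentation,
    stratified splits, and a confusion-matrix/ROC evaluation suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
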