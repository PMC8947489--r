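Package: wsimine
Title: Weakly Supervised Whole-Slide Image Classification with Hard Tile Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for training and evaluating weakly supervised binary
    classifiers of whole-slide histopathology images from slide-level labels
    alone. Implements Otsu-threshold tissue detection and tile-grid
    enumeration, balanced slide-queue tile sampling with oversampling,
    hard-example tile mining alternating with training, partial fine-tuning
    (batch-normalization affine parameters and classifier head only) of a
    pluggable convolutional backbone with Adam and a stepped learning-rate
    decay, sliding-window tile inference with max-aggregated slide scoring
    and jet-colormap probability heatmaps, and an evaluation suite with
    threshold-sweep ROC curves, AUC, log loss, confusion-matrix metrics, and
    percentile-bootstrap confidence intervals. Ships a synthetic slide
    generator with planted lesion textures so the full pipeline is testable
    without clinical data, and a command-line interface over the same
    functions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
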