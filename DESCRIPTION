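Package: sslcyto
Title: Iterative Semi-Supervised Labeling for Single-Cell Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A human-in-the-loop semi-supervised learning pipeline for classifying
    single-cell microscopy images, built around two candidate-selection strategies and
    their combination: confirmed self-training (high-confidence pseudo labels verified
    by an examiner before entering the training pool) and margin-sampling active
    learning (examiner labels requested for images whose top-two class probabilities
    are close). Includes class-balanced teacher-pool management with a per-class cap
    and recency priority, a compact squeeze-and-excitation convolutional reference
    classifier trained by SGD with momentum and warm starts across rounds, a
    rotation/flip/shift augmentation pipeline, a synthetic generator of morphologically
    distinct cell classes with a configurable simulated examiner, and evaluation
    statistics (merged-taxonomy confusion matrices, per-class recall/precision, and
    teacher-pool growth statistics across rounds).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    yaml,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
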