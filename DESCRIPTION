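Package: histoMPA
Title: Marine-Predators-Optimized Deep Belief Networks for Histopathology Tile Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for multiclass classification of
    histopathology image tiles (lung and colon carcinoma subtypes).
    Implements contrast-limited adaptive histogram equalization (CLAHE)
    preprocessing, a lightweight depthwise-separable convolutional feature
    extractor, the Marine Predators Algorithm (MPA) as a bounded continuous
    optimizer and classifier hyperparameter tuner, restricted Boltzmann
    machines stacked into a deep belief network with backpropagation
    fine-tuning, an optional stacked autoencoder compressor, one-vs-rest
    multiclass evaluation metrics, and a synthetic labeled-tile generator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
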