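Package: histofuse
Title: Stain Normalization, Pyramid Binary-Pattern Features, and Fused
    Deep-Classical Classification for Histology Tiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for five-class histopathology tile classification that fuse
    handcrafted texture descriptors with features learned by a small
    convolutional network. Provides Macenko-style stain normalization (SVD
    stain-matrix estimation in optical-density space), a global-local pyramid
    binary-pattern descriptor computed over a schedule of growing circular
    neighbourhoods, a depthwise-separable residual network with a custom
    feature-grafting layer that injects the handcrafted vector mid-network,
    classical classifiers (SVM, k-nearest neighbours, decision tree) on the
    fused features, a full multi-class evaluation suite, and a seeded
    generator of synthetic H&E-like tiles so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    caret,
    dplyr,
    e1071,
    generics,
    grDevices,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
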