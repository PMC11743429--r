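Package: tonguenet
Title: Region-Partitioned Multi-Branch Networks for Tongue Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the five-viscera health statuses (heart,
    lung, liver, spleen, kidney) from tongue photographs in the Traditional
    Chinese Medicine tradition. Provides a deterministic tongue-region
    partitioning algorithm (tip, margins, center, root), a five-branch
    multi-label convolutional classifier with per-organ average-voting
    fusion, an asymmetric focal-style loss for imbalanced labels, per-organ
    evaluation metrics, Grad-CAM inspection of trained branches, and a
    seeded synthetic tongue-image generator that plants region-localized
    diagnostic features so the whole pipeline is exercisable without
    clinical data. Includes a compact pure-R CNN engine (convolution via
    im2col on BLAS, AdamW, full backpropagation) so no external deep
    learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    EBImage
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
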