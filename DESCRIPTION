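Package: crcseg
Title: Multi-Class Tissue Segmentation and Biopsy Risk Classification for
    Colorectal Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage computer-aided diagnosis pipeline for colorectal
    cancer histopathology. Stage one is a U-Net style convolutional network
    that segments hematoxylin-eosin image tiles into fourteen tissue
    compartments and can be trained under four interchangeable objectives:
    categorical cross-entropy, focal loss, bi-tempered logistic loss, and the
    Lovasz-softmax surrogate of the Jaccard index. Stage two converts
    slide-level segmentation maps into one of four ordinal risk categories
    with a random forest over class-histogram and tumor-cluster features.
    Includes tile-based whole-slide inference with seam-free stitching,
    per-class Dice and benchmark-style F1 evaluation with class merging and
    lumen relabeling, quadratic weighted kappa and one-vs-all ROC analysis,
    and a synthetic tissue generator so the entire pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    pROC,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
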