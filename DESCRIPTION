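Package: fcoslsc
Title: Anchor-Free Green-Fruit Detection with Level-Space-Channel Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An anchor-free dense object detector for green fruit in green
    orchard canopies, built around a deformable-convolution ResNet50 backbone,
    a feature pyramid refined by a cascade of level (scale), spatial and
    channel attention, and a dual-weighting label-assignment loss that gives
    every candidate location both a positive and a negative supervision
    weight. Includes COCO-format data input/output and LabelMe conversion, a
    seeded synthetic-orchard scene generator for desk-scale experiments,
    an SGD training loop with warmup and step schedule, COCO-style mAP/mAR
    evaluation, and a symbolic parameter/FLOP complexity counter. All tensor
    operations run on a small reverse-mode automatic-differentiation engine
    with compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
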