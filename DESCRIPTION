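Package: nervect
Title: Anatomy-Aware 3D Segmentation of Peripheral Nerve MicroCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional semantic segmentation of peripheral
    nerve microCT volumes into background, fascicle and epineurium classes.
    Provides a synthetic plexiform-nerve phantom generator with a known
    split/merge event ledger, a 3D U-Net trained with a compound loss
    (cross-entropy + soft Dice + a topological-interaction penalty focused on
    voxels violating the fascicle-enclosure constraint), sliding-window
    inference with Gaussian-weighted patch blending, and an evaluation suite
    covering volumetric overlap (Dice), surface Dice, average symmetric
    surface distance, per-slice fascicle instance detection (F1 over IoU
    thresholds, over/under-segmentation, size-stratified miss rates),
    centerline Dice connectivity, anatomical error rate, inter-slice boundary
    consistency and split/merge event-rate deviation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    tibble,
    stats,
    utils,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
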