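Package: morphopipe
Title: Image-Based Morphological Profiling with Sphering Batch Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end workflow for image-based profiling of Cell
    Painting perturbation experiments: microscopy illumination correction
    and 16-to-8 bit compression, single-cell cropping and weakly
    supervised treatment classification, feature extraction from
    convolutional backbones, hierarchical profile aggregation
    (median/mean/mean), ZCA sphering batch correction fitted on negative
    controls, Z-score treatment-effect estimation, and retrieval-based
    biological evaluation (interpolated mean average precision and Fisher
    folds of enrichment).  A parametric synthetic-experiment generator
    with controllable phenotype effects and hierarchical technical
    confounders makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    yaml,
    cluster,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
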