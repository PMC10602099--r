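Package: microlumen
Title: Lumen Identification, 3D Reconstruction and Phenotypic Profiling
    of Glandular Microtissue Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated identification and volumetric analysis of luminal
    cavities in 3D microtissue z-stacks, together with a phenotypic
    image-feature profiling workflow. Per-slice binarization and iterative
    morphological closing over an increasing disk schedule expose candidate
    voids; a pluggable true/false lumen classifier filters them; surviving 2D
    lumens are grouped across slices by bounding-box overlap with gap
    splitting and reconstructed as alpha shapes whose volumes (um^3) and
    surface areas (um^2) are reported per microtissue. The profiling side
    provides range and power scaling, dose regrouping, OPLS-DA with
    VIP-based differential feature selection, random-forest classification
    with macro/micro multi-class AUC, and delta-delta-Ct fold-change
    arithmetic. Seeded synthetic-data generators for microtissue stacks
    with known lumens and for multi-class feature tables with planted
    effects provide ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    randomForest,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
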