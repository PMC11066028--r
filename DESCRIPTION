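Package: featscope
Title: Self-Supervised Protein Feature Profiles from Single-Cell Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns protein feature profiles from single-cell fluorescence
    micrograph crops with a convolutional network trained on the
    self-supervised pretext task of predicting protein identity, and provides
    the downstream analytics that turn those profiles into biology: synthetic
    micrograph simulation with known ground truth, watershed-based crop
    preparation, co-annotation benchmarking (average precision, F-score,
    adjusted mutual information), hierarchy cutting by the AMI-derivative
    rule, linear-probe localization mapping with SmoothGrad feature
    interpretation, single-cell localization heterogeneity (AND/OR) calling
    with cell-cycle association, and protein-complex discovery by adaptive
    dendrogram thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    MASS,
    cluster,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    nnet,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
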