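Package: apmsflow
Title: Interactor Calling, PTM Dynamics and Co-Regulation Clustering for
    AP-MS Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of affinity-purification mass-spectrometry
    (AP-MS) label-free quantification data: reading MaxQuant-style protein
    group and modification-site tables, identification filtering,
    detection-limit (downshifted Gaussian) imputation of missing values,
    Pearson-correlation control grouping, bait-versus-complement interactor
    calling with permutation-based false discovery rate control, bait- and
    protein-normalized quantification of dynamic protein-protein
    interactions and posttranslational modifications over activation time
    courses, co-regulation clustering of z-scored profiles, and assembly of
    annotated multi-bait interaction networks. Includes a synthetic AP-MS
    data generator with known ground truth (shared background binders,
    spiked interactors, intensity-dependent missingness, time-course
    profile classes) for benchmarking every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, Software
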