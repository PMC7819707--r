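Package: somadendrite
Title: Subcellular Single-Neuron Transcriptomics of Somata and Dendrites
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for subcellular single-cell RNA-seq experiments
    in which the soma and the dendritic arbor of individual neurons are
    captured and sequenced separately. Covers the full desk-side pipeline:
    a seeded synthetic-data generator with known ground truth, conversion of
    index+UMI barcoded read pairs into per-sample per-gene UMI count matrices
    (quality filtering, demultiplexing, edit-distance-1 UMI collapse),
    sample-level QC and ERCC spike-in detection-limit estimation,
    regularized negative-binomial residual normalization, PCA/SNN/Louvain
    cell-type identification with logistic-regression marker tests,
    cross-compartment differential expression with mock-permutation FDR
    calibration, paired soma-dendrite Poisson GLM enrichment tests,
    representation-score preranked gene set enrichment analysis, and
    smFISH dendrite intensity-profile punctum detection and raster plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
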