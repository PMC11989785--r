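Package: cocultalk
Title: Co-Culture Transcriptomics and Ligand-Receptor Crosstalk Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for mono- versus co-culture bulk RNA-seq
    experiments on two interacting cell populations. Provides FPKM
    normalization and sample-level quality control, a negative-binomial Wald
    test for differential expression with Benjamini-Hochberg correction and
    threshold-based DEG classification, hypergeometric over-representation
    analysis against user-supplied gene sets, degree-based hub ranking and
    spectral k-means module detection on interaction networks, and
    two-method autocrine/paracrine ligand-receptor pair inference ranked by
    communication scores (products of fold-change magnitudes). A seeded
    synthetic-data generator emulates the four-group, three-replicate study
    design with planted differential expression, ligand-receptor pairs and
    network modules for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    withr
Config/testthat/edition: 3
biocViews: RNASeq, DifferentialExpression, GeneExpression, Network,
    CellBiology, Transcriptomics
RoxygenNote: 7.3.3
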