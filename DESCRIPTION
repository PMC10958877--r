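Package: txcitools
Title: Processing and Simulation Tools for Pre-Indexed Droplet Single-Cell ATAC-seq
Version: 0.1.0
Authors@R: person("txcitools", "developers", role = c("aut", "cre"),
    email = "txcitools@example.org")
Description: Computational toolkit for droplet single-cell ATAC-seq with
    Tn5 pre-indexing (molecular hashing), in which an 8 bp plate-well barcode
    is inserted into chromatin fragments before nuclei are encapsulated in
    droplets, so that droplets containing several nuclei remain
    deconvolutable. Implements three-level barcode extraction, error
    correction and sample demultiplexing; alignment filtering and fragment
    deduplication on a hybrid two-species genome; barnyard species
    classification and corrected collision-rate estimation; per-cell quality
    metrics (fraction of reads in DNase hypersensitive sites, TSS
    enrichment, estimated library complexity); a Poisson droplet-loading
    simulator comparing molecular and cellular hashing throughput; a
    simulated-doublet detector for binarized peak-by-cell matrices; and an
    SNV-driven motif gain/loss analysis linking sequence variants to
    differential chromatin accessibility. A synthetic-fixture generator
    produces fully ground-truthed toy datasets for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    data.table,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
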