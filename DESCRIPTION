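Package: utarscan
Title: Discovery and Spatial Analysis of Unannotated Transcribed Regions
    in Spot-Based Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transcriptionally active regions (TARs) from
    spot-barcoded spatial transcriptomics alignments by segmenting binned,
    strand-specific genome coverage with a two-state hidden Markov model,
    classifies them against gene annotation into annotated (aTAR) and
    unannotated (uTAR) regions, labels uTARs by strand-specific overlap
    with long non-coding RNA reference sets, quantifies features per spot,
    scores marker-gene signatures, and tests uTARs for cell-type-specific
    differential expression with Wilcoxon rank-sum tests and
    Benjamini-Hochberg correction. Includes a synthetic-data generator
    that emulates FFPE RNA degradation (DV200) and poly(A) versus probe
    capture so that every pipeline stage can be validated against planted
    ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    ggplot2,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
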