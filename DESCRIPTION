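Package: WHAseq
Title: Window-Based HERV Alignment Analysis of Locus-Specific Endogenous
    Retrovirus Transcription
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Window-based HERV Alignment (WHA) procedure for
    calling locus-specific transcription of autonomous human endogenous
    retrovirus (HERV) loci from cell-type-partitioned single-cell RNA-seq
    reads. Each locus is tiled into sequential non-overlapping windows;
    reads are assigned to loci through a strict percent-identity alignment
    filter; loci are classified positive or negative from per-window read
    depth and the count of depth-passing ("usable") windows; duplicate
    technical runs are combined by consensus. Downstream cohort tools
    perform control-exclusion filtering, detection-frequency ranking,
    presence/absence matrix export, monocyte-subset intersection analysis,
    and host-gene window/depth group comparisons by one-way ANOVA with
    Tukey's HSD. A deterministic synthetic-data generator with planted
    locus activity provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, SingleCell, Coverage, Alignment, Sequencing
RoxygenNote: 7.3.3
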