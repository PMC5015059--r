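Package: hetflag
Title: Classification of Cell-to-Cell Expression Heterogeneity in
    Single-Cell RNA-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies per-gene cell-to-cell expression heterogeneity in
    single-cell RNA-seq data. For each gene the number of expressing cells
    (FPKM above a positivity threshold) is computed, genes within a
    moderate-expression window are pooled, and a two-component Gaussian
    mixture is fitted to the expressing-cell counts by EM; genes are flagged
    as high (H), low (L) or uncertain (U) heterogeneity by mixture posterior
    probability. Supporting tools cover union-exon gene lengths and FPKM from
    GTF annotation and count tables, RefSeq-prefix biotype rules with
    read-through exclusion, under/over FPKM bounds for genes overlapped by an
    opposite-strand gene in non-strand-specific data, coefficient-of-variation
    comparisons between lncRNAs and mRNAs with Welch's t-tests, a longest-ORF
    finder with a Monte-Carlo by-chance null, and a synthetic-data generator
    with planted ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'quantification.R'
    'mixture.R'
    'heterogeneity.R'
    'orf.R'
    'variation.R'
    'pipeline.R'
    'simulate.R'
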