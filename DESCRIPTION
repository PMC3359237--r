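Package: mirbean
Title: Small RNA-Seq miRNA Discovery, IsomiR Classification and
    Organ Expression Profiling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end re-usable pipeline for annotating microRNAs from
    multi-organ plant small RNA sequencing libraries without a reference
    genome. Reads are cleaned, collapsed to unique tags and filtered against
    a non-miRNA ncRNA set; conserved miRNAs are annotated by exact identity
    to a mature reference set and subjected to a two-library/15-read
    conservation filter; sequence and length variants (isomiRs) are detected
    by bounded fuzzy matching, abundance-filtered and classified; stem-loop
    precursors are located in EST/GSS sequences and validated by a
    nearest-neighbour free-energy folding engine; novel miRNA candidates are
    scored from read signatures including mature-star evidence; targets are
    predicted by intermolecular duplex free-energy minimisation with G:U
    wobbles; and family-level expression is normalised by median-of-ratios
    size factors, variance-stabilised and hierarchically clustered. A seeded
    synthetic-data generator with full ground truth makes every stage
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    jsonlite
biocViews: Sequencing, SmallRNA, Annotation, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
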