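Package: tadscope
Title: Paired RNA-Seq Differential Expression, Co-Expression Modules,
    RNA Regulatory Networks and TAD-Based Risk-Locus Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for dissecting the genetics of keloid
    disorder (and similar paired lesion/normal designs): paired
    negative-binomial differential expression for mRNA, lncRNA and miRNA
    count data; Pearson-correlation lncRNA-mRNA pairing and weighted
    co-expression (topological-overlap) module detection; assembly and
    degree-ranking of typed miRNA-lncRNA-mRNA regulatory networks; Fisher's
    exact gene-set enrichment; insulation-score TAD calling on Hi-C contact
    matrices; and mapping of GWAS susceptibility loci to the topologically
    associating domains (TADs) that contain them to prioritize
    differentially expressed RNAs. A synthetic-data generator with
    machine-readable ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2
Config/testthat/edition: 3
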