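Package: primaryTx
Title: Primary Transcriptome Analysis from Differential RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping and analysing the primary transcriptome of a
    bacterium from differential RNA-seq (dRNA-seq). Calls transcription start
    sites (TSSs) from stranded 5'-end profiles of 5'-pyrophosphatase-treated
    (RPP+) and untreated (RPP-) libraries using median-of-ratios scaling,
    peak clustering, twofold enrichment filtering and replicate consensus;
    classifies TSSs as primary, secondary, internal, antisense or intergenic
    relative to gene annotation; extracts 5'-UTRs and locates -10/-35
    promoter boxes and Shine-Dalgarno motifs by mismatch-tolerant consensus
    scanning; folds 5'-UTRs under a simplified nested-pairing energy model
    with an exhaustive oracle; and groups condition-responsive genes with a
    negative-binomial Wald test, BH-FDR and K-means clustering. A synthetic
    data module generates genomes, end profiles and count matrices with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
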