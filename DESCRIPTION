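Package: crestscan
Title: Cross-Population Selection Scans Linked to Developmental
    Expression Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects signatures of recent positive selection from phased
    two-population haplotype panels with the cross-population extended
    haplotype homozygosity statistic (xpEHH), merges significant sites
    into selection islands and links each island to its closest annotated
    gene, quantifies between-species expression divergence across
    developmental stages with median-of-ratios normalization, a
    negative-binomial Wald test and complete-linkage clustering of
    Z-scored temporal profiles, and tests expression clusters for
    enrichment of selection signal with a permutation null over
    size-matched windows upstream of transcription start sites. Forward
    Wright-Fisher haplotype simulators with controllable hard sweeps,
    a clustered negative-binomial count simulator and a gene-annotation
    simulator provide ground-truth data so every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    GenomicRanges,
    IRanges,
    mclust,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
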