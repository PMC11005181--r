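Package: chromlink
Title: Dominance-Based Classification and Distance-Correlation Linking of
    Regulatory Chromatin
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Separates developmental from housekeeping gene regulatory
    programs in three-lineage pseudo-bulk multi-omic data. Genes are
    classified into lineage-specific differentially expressed genes (DEGs)
    and similarly expressed genes (SEGs) with the Berger-Parker dominance
    index; chromatin accessibility and DNA methylation windows are called
    into differential/similar regions (DARs/SARs, DhMRs/ShMRs) by the same
    statistic; genome and TAD architecture statistics contrast the two
    programs; the chromatin abundance coefficient (CAC) links distal
    accessible regions to their target genes through a TAD-constrained
    zone-of-influence scan; and transcription-factor motif repertoires of
    the resulting regulatory neighbourhoods are compared with quartile-rank
    vectors, RMSE similarity and GC-stratified permutation tests. A
    synthetic multi-omic data generator with planted ground truth makes the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, GeneRegulation, ATACSeq, DNAMethylation,
    DifferentialExpression, Software
RoxygenNote: 7.3.3
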