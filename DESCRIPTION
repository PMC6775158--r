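Package: regenGRN
Title: Temporal Integration of RNA-seq and ATAC-seq for CNS Axon-Regeneration
    Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a CNS-regeneration time course combining bulk
    RNA-seq and ATAC-seq: negative-binomial differential expression against an
    uninjured baseline with Benjamini-Hochberg FDR control, K-means clustering of
    standardized (Z-score) temporal TPM profiles, construction and annotation of
    fixed-width accessible-chromatin peaklets, differential accessibility testing,
    log-odds PWM motif scanning of peaklet sequences, per-cluster stage-specific
    motif enrichment and co-occurrence networks, and motif-based inference of
    transcription-factor target genes. Includes a synthetic-data generator with a
    ground-truth manifest so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster
Config/testthat/edition: 3
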