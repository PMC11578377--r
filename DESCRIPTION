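Package: markshift
Title: Knockout-Lost Binding Domains and Histone Mark Redistribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of two-condition chromatin profiling
    (CUT&Tag or ChIP-seq style) together with RNA-seq. Calls
    knockout-lost binding domains for a factor on a fixed genome-wide
    window grid, quantifies co-occupancy of a second factor over those
    domains by log-scale Pearson correlation, assigns H3K27Ac and HDAC1
    signal to strand-aware gene regions (promoter, super-enhancer, gene
    body, whole gene) with ROSE-style super-enhancer calling, flags
    per-gene mark gain and loss by RPKM fold change, calls
    differentially expressed genes from a count matrix with TPM-based
    fold-change and p-value cutoffs, and combines the pieces into gene
    set overlap statistics with hypergeometric enrichment. Ships a
    deterministic synthetic epigenome generator with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
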