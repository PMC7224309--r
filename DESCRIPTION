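Package: identiscape
Title: Epigenomic and Transcriptomic Quantification of Tissue-Identity Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls tissue-identity genes from broad H3K4me3 domains, classifies
    differential H3K27ac regions from bin-level statistics, identifies
    super-enhancers by rank ordering, stratifies enhancer inactivation by
    transcription-factor co-binding degree, computes identity-loss expression
    statistics (scaled fold changes, bagplots, repression-quartile enrichment,
    gene-set enrichment scores), and projects perturbed transcriptomes onto a
    developmental principal-component axis. Ships a seeded synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
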