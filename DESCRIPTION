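Package: mitoduo
Title: Simulation and Diagnostics for Doubly Uniparental Mitochondrial Inheritance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying doubly uniparental inheritance (DUI) of
    mitochondria in bivalves, where a female-transmitted (F) and a
    male-transmitted (M) mitogenome lineage coexist within one species.
    Provides a seeded generator of annotated mitotype genome pairs with
    rate-heterogeneous divergence and lineage-specific structural events,
    a read simulator, fixed-difference and sliding-window divergence
    scanning of group alignments, p-distance with bootstrap standard
    errors, in-silico multiplex PCR with amplicon-size mitotype
    classification, diagnostic k-mer read typing with homoplasmy calling,
    qPCR standard-curve quantification with geometric-mean normalization
    and tissue-level mitotype calls, and nonparametric mitotype/sex effect
    statistics on enzyme activities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
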