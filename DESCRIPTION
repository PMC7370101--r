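Package: aqpkit
Title: Aquaporin Family Annotation, Selectivity Signatures, and Substrate Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize plant aquaporin (major intrinsic protein)
    families from protein sequences, gene models, and expression tables:
    hydropathy-based transmembrane segmentation, NPA motif anchoring and a
    completeness screen for pseudogene-like candidates, nearest-reference
    subfamily/group classification (PIP, TIP, NIP, SIP, XIP) with an optional
    neighbor-joining tree, extraction of the ar/R selectivity filter and
    Froger's positions, substrate prediction from position-wise
    residue-class patterns (boron, CO2, H2O2, ammonia, silicon, urea,
    arsenic, antimony), intron/exon structure summaries, and FPKM-threshold
    expression calling. Ships machine-readable transcriptions of a tobacco
    aquaporin gene inventory and substrate-specificity pattern table, plus a
    deterministic synthetic-data generator with ground-truth manifests so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
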