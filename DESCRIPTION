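Package: enhancerDissect
Title: Quantitative Cis-Regulatory Dissection of Notochord Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative dissection of compact developmental
    enhancers, built around the proximal Ciona brachyury enhancer as the
    motivating case. Provides JASPAR-format position weight matrix parsing,
    log-odds scanning with exact match p-values computed by dynamic
    programming, constraint-driven design of transition-substitution
    knockouts of predicted transcription factor binding sites with rescan
    verification, dual-reporter image quantitation with
    electroporation-efficiency normalization and lineage-resolved ratios,
    single-cell mosaicism versus graded-expression analysis, and seeded
    synthetic-data generators for sequences, embryo and cell intensity
    tables, and renderable confocal-like image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
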