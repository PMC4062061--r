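Package: varconcord
Title: Variant Consequence Annotation and Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A rule-based variant consequence annotator over explicit
    transcript models, with two configurable definitional regimes emulating
    the vocabulary and splicing/precedence conventions of widely used
    annotation tools, harmonization of consequence terms into high-level
    categories (loss-of-function, missense, synonymous, non-exonic), and
    concordance statistics for pairs of annotation runs: per-term and
    rolled-up match rates, union counts, and log/z-normalized
    cross-tabulation matrices. Includes a seeded synthetic-data generator
    producing genomes, diverging transcript set pairs and variants with
    designed ground-truth consequences, so every pipeline stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
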