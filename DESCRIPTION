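Package: svcurate
Title: Structural Variant Evidence Visualization and Curation Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for reviewing structural variant (SV)
    calls against the raw alignment evidence. Extracts paired-end and
    split-read alignments and per-base coverage from indexed BAM files for
    the window around each candidate SV, classifies every observation by
    the rearrangement it supports (deletion, duplication, inversion),
    renders stacked per-sample evidence images with an annotation track,
    and manages a local curation project: configurable question/answer
    schemes, response capture, curation-score aggregation, tab-delimited
    reports, score-annotated VCFs, and concordance analysis against
    orthogonal genotype and copy-number calls. Includes a synthetic
    alignment generator that plants DEL/DUP/INV signatures in trio samples
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    patchwork,
    jsonlite,
    withr,
    generics,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
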