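Package: mpraduo
Title: Analysis of Dual-Element Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dual-element massively parallel reporter assays
    (MPRAduo-style designs pairing an activating element with a silencer
    candidate on one construct). Covers barcode-to-oligo dictionary
    construction from association amplicons, single/duo tag-read
    classification and counting, median-of-ratios normalization with
    summit-shift and quantile normalization of log2 RNA/DNA activities,
    silencer calling against negative controls, allelic-skew (emVar)
    testing, position-weight-matrix scanning with half-site spacer and
    orientation classification, piecewise change-point estimation of the
    motif-intrinsic score boundary (m-value), a log-additive interaction
    model for duo activities, and a seeded synthetic-experiment generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
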