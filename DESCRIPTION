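Package: hichipr
Title: Desk-Scale Analysis of HiChIP Chromatin-Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for the downstream analysis of
    protein-directed chromatin-interaction (HiChIP-style) experiments:
    spike-in (reference-exogenous) normalization of read and PET counts,
    in-silico restriction digestion with linker-aware read trimming and
    valid-pair classification, loop filtering and priority-ordered
    functional annotation of anchors, anchor-level overlap classification
    between two loop sets, PWM motif scanning with exact p-values,
    promoter-hub network reconstruction with cluster statistics and
    gene-set over-representation, and signal-integration statistics
    (windowed counting, metagene densities, equal-size binning,
    reference-median normalization). A synthetic-data module generates
    every pipeline input with known planted truth so the whole stack is
    exercisable, and testable, without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
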