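Package: zgakit
Title: Chromatin State, CRE Linkage and RNAPII Pausing Analysis for Early
    Embryo Multiome and CUT&Tag Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing spike-in normalized CUT&Tag chromatin
    profiles and 10x-style single-cell multiome (RNA + ATAC) data from
    early Drosophila embryos. Implements lambda spike-in and total-H3
    normalization of mark libraries, cross-stage classification of
    H3K27me3/H3K27ac "ambivalent" chromatin states, background-matched
    peak-to-gene linkage with promoter/enhancer assignment and
    expression-accessibility correlation comparisons, germ-layer gene
    identity scoring, and an RNA polymerase II promoter-proximal pausing
    index. Ships a synthetic-data generator that emulates the statistical
    structure of such experiments (germ-layer-driven expression, planted
    enhancers, mutually exclusive per-cell-type histone marks, depth and
    nuclei confounding, tunable pausing) so every estimator can be tested
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
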