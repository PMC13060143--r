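Package: crekit
Title: Functional Characterization of Cis-Regulatory Elements in T Cells
Version: 0.1.0
Authors@R:
    person("crekit", "maintainers", email = "crekit@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and dissecting the regulatory activity of
    open chromatin regions across related cell states. Implements sliding-window
    STARR-seq enhancer activity calling against an input DNA library
    (fragment-length filtering, window counting, negative-binomial testing,
    window merging and region-level p-value combination), a star-coordinate
    projection that classifies regions as subset-preferred or shared across
    conditions, CRISPR tiling guide library design with accessibility-ranked
    greedy selection and GC-matched non-targeting controls, sorted-bin screen
    count analysis with element-level aggregation, and contact-matrix utilities
    (ICE balancing, observed/expected normalization, aggregate peak analysis,
    differential maps). A synthetic-data module generates every input with
    planted ground truth so that each stage can be exercised and validated
    end-to-end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
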