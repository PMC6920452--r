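Package: haplospat
Title: Spatial Distribution Analysis of mtDNA Haplotypes in Invasive Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether mitochondrial haplotypes are distributed
    at random across sampling locations, built around a fixed-margin
    contingency-table randomization test with per-cell effect statistics,
    permutation P-values and false-discovery-rate control. Includes haplotype
    calling from COI amplicon sequences with pseudogene (NUMT) screening,
    haplotype and nucleotide diversity estimators, distance-based population
    structure summaries (pairwise Phi-ST and hierarchical AMOVA), a null-model
    self-validation harness, and a synthetic-data generator so the whole
    pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
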