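Package: mirheat
Title: Conserved Sex-Biased microRNA Markers of Thermal History in Fish Gonads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for nominating gonadal microRNA (miRNA)
    "heat-recorder" markers in fish with temperature-sensitive sex
    determination. It couples a negative-binomial Wald differential-expression
    stage for a four-group (sex x temperature) small-RNA experiment with a
    cross-species seed-region conservation analysis over ten fish species, a
    deterministic log2(testis/ovary) sex-bias classification rule, and the
    intersection of the two that flags conserved sex-biased miRNAs still
    differentially expressed long after an early-life heat treatment. A
    synthetic-data module simulates the focal experiment and the ten-species
    ovary/testis panel with planted effects so every stage is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
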