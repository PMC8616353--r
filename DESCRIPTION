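Package: glycofab
Title: Integrated N- and O-Glycomics Trait Analysis for Leukemia Cell-Line Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated N- and O-glycomics of cell-line cohorts:
    parsing and validation of glycan composition strings (Hex/HexNAc/Fuc/NeuAc
    with phosphorylation and sulfation), composition-based glycan-type
    classification, derivation of structural glycan traits (glycan types,
    sialylation linkages, fucosylation, bisection, Lewis-type antigens) from
    fractional abundances, quantification quality control and normalization,
    principal component analysis with Hotelling T-squared limits, trait-gene
    Pearson correlation, regularized canonical correlation analysis against
    transcription-factor panels, and a seeded synthetic multi-omics cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
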