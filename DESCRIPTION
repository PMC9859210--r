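Package: folatrio
Title: Gene-Folate Interaction Analysis in Case-Parent Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Family-based statistical toolkit for studies of congenital
    heart defects and folate-pathway genetics in case-parent trios.
    Implements the exposure-stratified log-linear model of maternal and
    fetal genotype relative risks (Weinberg-Umbach construction) with an
    EM algorithm for incomplete families, gene-environment interaction
    tests, fixed-effect inverse-variance meta-analysis across study
    phases with Bayesian false-discovery probability (BFDP) ranking,
    an exact binomial test for de novo mutation enrichment computed in
    log space, region-based rare-variant tests (transmission burden and
    a family-based kernel score test), trio quality control (Mendelian
    screening, call-rate and concordance filters), VCF/PED hard-filter
    input handling, and a trio simulator that emulates the study design
    for power and calibration work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    metafor,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
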