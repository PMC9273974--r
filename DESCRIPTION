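Package: rusitecr
Title: Analysis Toolkit for Rusitec Seaweed Supplementation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the quantitative analysis of rumen simulation
    technique (Rusitec) experiments that test brown seaweed inclusion in a
    total mixed ration: dry-matter-basis diet formulation, gas and methane
    summaries, feed-bag nutrient degradation and effluent metabolite mass
    balances, 15N isotope-dilution partitioning of microbial nitrogen with
    estimated microbial protein synthesis (EMPS), mixed-design treatment
    inference with Fisher's LSD letters, amplicon feature-table diversity
    and group testing, and a synthetic-data generator with known ground
    truth so every stage is testable without experimental downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
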