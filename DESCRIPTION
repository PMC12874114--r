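Package: mnpsdiet
Title: Diet-Level Nutrient Profiling for Older Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes diet-level diet-quality scores for older adults from
    daily dietary intake records of the kind produced by brief diet-history
    questionnaires. Implements the Meiji Nutritional Profiling System for
    Older Adults (MNPS-OA) in four model variants (original, without energy
    limit, without nutrient caps, and without both), together with the
    comparison indices HEI-2015, NRF9.3 and the Diet Quality Score for
    Japanese (DQSJ), the density-method energy adjustment, eligibility
    filtering, energy-percentage sugar imputation, and a Spearman-based
    construct/convergent validity analysis. Ships a seeded synthetic cohort
    generator that emulates the right-skewed, energy-correlated intake
    structure of questionnaire data so every stage is testable without
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
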