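Package: fsdcase
Title: Functional Somatic Disorder Case Classification for Questionnaire Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Operationalises the EURONET-SOMA functional somatic disorder (FSD)
    diagnosis for population questionnaire cohorts. Applies instrument-specific
    rules (Widespread Pain Index, ROME-III, CDC Symptom Inventory, Checklist
    Individual Strength, SCL-90 somatization over two waves) to decide whether
    each symptom is persistent (at least six months) and troublesome (moderate
    to severe impact), classifies respondents into single-symptom,
    single-system and multi-system diagnostic subgroups, computes optional
    specifiers (same-system chronic disease, concurrent psychiatric diagnoses,
    functional somatic syndromes), compares subgroups with Kruskal-Wallis,
    epsilon-squared, Dunn-Bonferroni post hoc tests, chi-square and Cramer's V,
    and fits a cross-validated elastic-net logistic regression for predictors
    of caseness. A synthetic cohort generator with planted ground truth stands
    in for access-restricted population data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
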