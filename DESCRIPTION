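Package: roctree
Title: Kappa-Maximizing ROC Recursive Partitioning for Treatment-Outcome
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds clinical prediction rules for antidepressant treatment
    remission from structural-MRI feature tables by ROC signal-detection
    recursive partitioning: every observed value of every candidate
    predictor is evaluated as a cut-point, scored by Cohen's kappa against
    the remission label, and the best significant split (Fisher exact
    p < 0.01) is applied recursively.  Includes independent-cohort
    validation via exact binomial replication and better-than-chance
    tests, 1000x100 subsampling cross-validation of rule specificity,
    serial and parallel combination of decision trees, group
    characterization tables, and a seeded synthetic cohort generator that
    plants known decision trees into AAL-atlas gray-matter volumes and
    JHU ICBM-DTI-81 tract fractional-anisotropy features so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
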