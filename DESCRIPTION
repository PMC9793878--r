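Package: crossbiome
Title: Cross-Cohort Microbiome Meta-Analysis with Batch-Aware Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of multi-cohort amplicon microbiome
    surveys in case-control designs. Provides a synthetic multi-cohort count
    simulator with planted disease effects and study-level batch effects;
    taxonomy-aware filtering, genus aggregation and cohort merging of feature
    tables; centered log-ratio (CLR) and rank transforms; rank-based variance
    decomposition contrasting disease status against confounders (study, age,
    BMI, sample type); Bray-Curtis ordination and composition summaries;
    Welch's t and Wilcoxon differential-abundance testing with biomarker
    overlap sets; and random-forest classifiers evaluated by stratified
    cross-validation, leave-one-cohort-out validation and cohort-to-cohort
    transfer AUC matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    randomForest,
    car,
    vegan,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
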