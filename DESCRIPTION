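Package: hemodiscrim
Title: Discrimination of Iron Deficiency Anemia from Beta-Thalassemia
    Trait with Hematological Indices and Decision Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing methods that discriminate iron deficiency
    anemia (IDA) from beta-thalassemia trait (bTT) on complete blood count
    (CBC) panels. Ships a declarative registry of 43 published
    discrimination indices (Mentzer, Green & King, Shine & Lal and
    relatives), a conjunctive threshold rule engine including the published
    six-leaf CRUISE decision rules, a demonstrative greedy Gini tree
    fitter, a thirteen-measure diagnostic accuracy suite with confidence
    intervals and ROC/AUC comparison, a summary-statistics-to-confusion
    matrix reconstruction oracle, method-similarity analysis via classical
    multidimensional scaling and complete-linkage clustering with
    majority-vote cluster-count selection, and a synthetic CBC cohort
    generator for end-to-end testing when patient data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
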