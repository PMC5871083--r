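Package: lupuscc
Title: Coagulation-Complement Pathway Scores and D-Dimer/C4 Diagnostics
    for Lupus Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Composite coagulation, complement and inflammatory-cytokine
    pathway scores from ELISA analyte panels in systemic lupus
    erythematosus; interaction (effect-modification) analysis of the two
    pathway scores on log-transformed SLEDAI disease activity, with
    median-split stratified comparisons (LSD or Tamhane T2 routed by
    Levene's test) and cytokine-subgroup moderation; a quartile-coded
    logistic diagnostic model combining plasma D-dimer and serum C4,
    including the 16-cell odds-ratio grid, a built-in predictive equation
    with its cut-off performance table (sensitivity, specificity, PPV,
    NPV, Youden index), and ROC/AUROC comparison against single markers.
    Ships a synthetic-cohort simulator so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
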