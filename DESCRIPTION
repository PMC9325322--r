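Package: pimddi
Title: Screening Oral Anticoagulant Use for Inappropriate Medications,
    Drug Interactions and Bleeding Risk in the Elderly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacoepidemiology pipeline for elderly patients on oral
    anticoagulants across the primary-care/hospital transition. Builds drug
    eras from dispensing and administration records, screens them against a
    curated knowledge base for potentially inappropriate medications (Beers
    criteria), bleeding-risk drug-drug interactions and their overlap
    (PIM-DDI), phenotypes hospitalizations for bleeding adverse drug events
    from ICD-10 diagnoses, INR and hemoglobin results and antidote
    administration, classifies anticoagulant treatment pathways, and models
    bleeding risk with multivariable logistic regression and SMOTE-rebalanced
    tree and kernel classifiers. Ships a synthetic linked-cohort generator
    with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
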