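Package: skinsens
Title: Two-Stage Bagged Gradient-Boosting Prediction of Human Skin
    Sensitization Hazard and Potency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating a two-stage defined
    approach to human skin sensitization: substances are first classified
    as sensitizer versus non-sensitizer, and predicted sensitizers are
    then graded strong (1A) versus weak (1B). Each stage is a bagged
    ensemble of five gradient-boosted tree classifiers tuned by
    cross-validated balanced accuracy and combined by majority vote.
    Inputs integrate in vitro assay readouts (DPRA peptide depletion,
    KeratinoSens EC1.5, h-CLAT, SENS-IS), physicochemical descriptors,
    and a scalar feature pooled from SMILES language-model embeddings.
    Includes correlation-based descriptor pruning, stratified splitting,
    feature selection by averaged gain importance with assay
    substitution, confusion-matrix metrics and AUC variants, a 3-class
    potency report with under/over-prediction rates, applicability-domain
    flags, averaged SHAP attributions, and a synthetic data generator
    emulating the structure of the Cosmetics Europe dataset.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
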