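Package: thoraxcomp
Title: Thoracic CT Body Composition Quantification and Survival Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Opportunistic body-composition analysis of thoracic CT
    attenuation maps. Separates the body into intrathoracic and
    extrathoracic compartments with a slice-wise convex hull over the
    intrathoracic organs, attributes voxels to skeletal muscle, bone, and
    four adipose depots (subcutaneous, intermuscular, visceral, epicardial)
    from Hounsfield-unit ranges, and standardizes volumes to the T5-T11
    vertebral slab with body-surface-area indexing. Includes a thoracic CT
    phantom generator with exact ground truth, a survival-cohort simulator
    with known per-SD log-hazards, and the downstream risk analysis:
    sex-specific Youden cut-points, per-SD Cox models with likelihood-ratio
    chi-square increments, stratified Kaplan-Meier curves, Fine-Gray
    competing-risk models for myocardial infarction, and proportional-hazards
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    survival,
    cmprsk,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
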