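Package: RadioGliomics
Title: VASARI and ADC Radiomics Fusion Modelling of IDH1 Genotype in
    Lower-Grade Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting IDH1 mutation status in lower-grade
    gliomas from qualitative VASARI scores and quantitative apparent
    diffusion coefficient (ADC) radiomics. Implements 56-feature
    radiomics extraction (shape, first-order histogram, GLCM, GLRLM,
    GLSZM and NGTDM families) from masked 3-D volumes, encoding and
    validation of the 23-trait VASARI lexicon, two-step feature
    selection combining minimum-redundancy maximum-relevance ranking
    with 0.632+ bootstrap AUC estimation, random-forest model-order
    sweeps, decision-level probability fusion, Dice segmentation
    agreement and cohort-balance statistics. A seeded synthetic cohort
    generator with plantable class effects makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
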