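Package: metaboSIMCA
Title: One-Class SIMCA Screening for Untargeted LC-HRMS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Preprocessing and one-class classification of untargeted
    LC-HRMS metabolomics peak tables, aimed at detecting fentanyl intake
    from indirect alterations of the urinary metabolome. Implements
    sparsity filtering, total-area / internal-standard / pool-profile
    normalization, log transformation and scaling, replicate screening by
    principal component analysis, PCA with venetian-blinds
    cross-validation and Hotelling T2 / Q-residual diagnostics, one-class
    SIMCA with discriminant-power variable selection and an RMSECV-driven
    choice of model order, serial fusion of reverse-phase and HILIC
    decisions, and a synthetic-study generator reproducing the designs the
    method was developed on.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'core_tables.R'
    'latent_models.R'
    'simca.R'
    'pipeline.R'
    'preprocess.R'
    'synthetic_study.R'
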