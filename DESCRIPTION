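Package: nawmrad
Title: Longitudinal Radiomics of Normal-Appearing White Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for longitudinal FLAIR radiomics of
    normal-appearing white matter (NAWM). Constructs developing-NAWM regions of
    interest by subtracting baseline from follow-up white-matter-hyperintensity
    masks, extracts a histogram / shape / gray-level co-occurrence (GLCM) /
    run-length (RLM) texture-feature battery at multiple angles and offsets,
    reduces dimensionality with a univariate ANOVA plus Mann-Whitney filter,
    Spearman redundancy pruning and LASSO-penalized logistic selection, fits
    multivariable logistic models for the three tissue contrasts, and evaluates
    them with ROC/AUC, Hosmer-Lemeshow calibration and intraclass correlation.
    Includes a seeded synthetic-cohort generator of textured image pairs so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    pROC,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
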