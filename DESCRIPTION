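Package: octroc
Title: Covariate-Adjusted ROC Regression for OCT Glaucoma Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools to quantify how disease severity, age, refraction, axial
    length and optic-disc size modulate the glaucoma-diagnostic accuracy of
    optical coherence tomography (OCT) thickness markers. Implements the
    probit ROC-GLM (Alonzo-Pepe placement-value) regression with closed-form
    binormal AUROC, stratified bootstrap inference, Bennett ocular
    magnification correction of measured optic-disc area, Humphrey 30-2
    visual-field reliability and defect-cluster classification, cohort
    eligibility filtering, group-comparison tables, and a synthetic
    case-control cohort generator whose true covariate-specific ROC follows
    the fitted model, so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
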