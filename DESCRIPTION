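Package: radfusion
Title: Radiomics and Deep-Feature Fusion for Cerebrospinal-Fluid Signal Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying infected versus non-infected cerebrospinal-fluid
    related regions on 2D MRI slices. Implements multiscale radiomics extraction
    (first-order, 2D shape, and GLCM/GLSZM/GLRLM/NGTDM/GLDM texture features from
    original and Laplacian-of-Gaussian filtered images), filter-based feature
    selection, a dual-branch convolutional network that fuses atrous-spatial-
    pyramid-pooled image features with selected radiomics features, nested
    patient-grouped cross-validation with two-phase training, and strict
    patient-wise clinical decision rules. Includes a synthetic phantom cohort
    generator so the full pipeline is exercisable without clinical data.
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
    pROC,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
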