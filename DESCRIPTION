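Package: encrad
Title: Encrypted Multi-Region CT Radiomics for Treatment-Response Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, privacy-aware CT radiomics pipeline for
    treatment-response stratification in non-small cell lung cancer. From
    tumor volumes and segmentation masks it derives three analysis regions
    (largest axial slice, full 3D tumor, 3 mm peritumoral shell), encrypts
    them losslessly with AES-256-CBC and audits fidelity (SSIM) and
    security (directional pixel correlation), extracts IBSI-family
    radiomic features (shape, first-order, GLCM, GLRLM, GLSZM, NGTDM,
    GLDM, plus stationary-wavelet sub-band variants), selects features by
    a Mann-Whitney/Benjamini-Hochberg, mRMR and cross-validated LASSO
    cascade into a radiomics score (RadScore), builds clinical, regional
    and combined classifiers with repeated stratified cross-validation,
    bootstrap AUC intervals, DeLong comparisons and decision-curve
    analysis, and stratifies biomarker rates by RadScore tertiles. A
    synthetic phantom-cohort generator with controllable intratumoral and
    peritumoral texture effects makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    e1071,
    ranger,
    xgboost,
    class,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    digest,
    openssl,
    pROC
Config/testthat/edition: 3
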