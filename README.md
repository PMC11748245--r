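# encrad

Privacy-aware multi-region CT radiomics for treatment-response modeling in
non-small cell lung cancer (NSCLC).

Predicting who will respond to EGFR tyrosine-kinase inhibitors (EGFR-TKIs)
or immune checkpoint inhibitors (ICIs) currently requires invasive
molecular testing (EGFR mutation subtyping, PD-1/PD-L1 tumor proportion
scores). Radiomics offers a noninvasive alternative: quantitative texture
and shape features mined from routine CT. Two practical obstacles stand in
the way — medical images are sensitive data that must be protected when
they move between sites, and single-region tumor features ignore the
peritumoral microenvironment. `encrad` implements a complete, tested
pipeline that addresses both:

1. **Region derivation** — from a 3D tumor mask it builds three regions of
   interest: the largest-area axial slice (resampled to 0.8 mm in-plane),
   the full 3D tumor, and the peritumoral shell within 3 mm of the tumor
   boundary (both at 1.0 mm isotropic).
2. **Lossless encryption** — each region is serialized canonically and
   encrypted with AES-256 in cipher-block chaining (CBC) mode. The round
   trip is bit-exact (SSIM = 1), and audits confirm that adjacent-pixel
   correlations of the ciphertext vanish in the horizontal, vertical and
   diagonal directions.
3. **Feature extraction** — IBSI-family radiomics per region: 14 shape,
   19 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 14 GLDM
   features (108 per region from the original image), plus the same
   intensity families from each one-level stationary coif1 wavelet
   sub-band. Every texture feature is pinned against an independent
   brute-force enumeration oracle in the test suite.
4. **RadScore** — a three-step selection cascade fitted on the training
   split only: Z-score normalization, Mann-Whitney U screening with
   Benjamini-Hochberg FDR (5%), minimum-redundancy maximum-relevance
   (mRMR) ranking, and LASSO-penalized logistic regression with the
   penalty chosen by 5-fold cross-validated misclassification error. The
   radiomics score is the linear combination

   `RadScore = b0 + sum_j b_j * z_j`

   over the selected normalized features.
5. **Models and evaluation** — clinical (backward-AIC covariate
   selection), three regional radiomics models, and a combined
   radiomics-clinical model, built with any of seven classifiers
   (logistic, linear/RBF SVM, random forest, gradient boosting, kNN,
   naive Bayes); evaluated by AUC with 1000-sample bootstrap CIs, DeLong
   tests, Youden-threshold accuracy/sensitivity/specificity, 30×5
   stratified repeated CV, and decision-curve analysis
   (`NB(pt) = TP/n − FP/n · pt/(1−pt)`).
6. **Biomarker stratification** — RadScore tertile groups (boundaries from
   the training set), per-group mutation/expression rates, and Spearman
   correlation of RadScore with each therapy-response label.

Because real patient cohorts cannot ship with a package, `encrad` includes
a synthetic phantom-cohort generator: ellipsoidal tumors in noisy
lung-like volumes whose intratumoral and peritumoral texture statistics,
clinical covariates and label prevalences (EGFR 38.5%, 19Del 19.1%, L858R
14.9%, T790M 9.2%, PD-1/PD-L1 47.1%) are controllable, so every stage of
the pipeline is exercised end to end without any download.

## Worked example

```r
library(encrad)

spec <- phantom_spec(n_patients = 120, rng_seed = 42,
                     intratumoral_texture_shift = c(EGFR = 1.2))
cohort  <- generate_cohort(spec)
splits  <- split_cohort(cohort, 0.6, stratify_on = "EGFR", seed = 1)

key  <- rad_key(paste(rep("2b", 32), collapse = ""))
cfg  <- extraction_config(wavelet = FALSE)
features_tr <- extract_cohort(splits$train, cfg, key = key)
features_te <- extract_cohort(splits$test,  cfg, key = key)

rs <- fit_radscore(features_tr[-1], splits$train$labels$EGFR, seed = 1)
glance(rs)
#> # A tibble: 1 × 5
#>   region   n_screened n_mrmr n_selected lambda
#>   <chr>         <int>  <int>      <int>  <dbl>
#> 1 combined         62     30          4  0.164

scores <- compute_radscore(rs, features_te)
roc_auc(scores, splits$test$labels$EGFR)
#> [1] 0.7336861
```

`glance(rs)` reports the cascade's funnel: 62 of the 324 features survive
the FDR screen, mRMR keeps 30, and the LASSO at its cross-validated
penalty (lambda = 0.164) retains 4 with nonzero coefficients. The held-out
AUC of 0.73 reflects the modest 1.2 SD texture effect implanted in this
small (n = 120) synthetic cohort — with no implanted effect the same
pipeline yields AUC close to 0.5, and at n = 300 with a 1.5 SD shift it
exceeds 0.8 (see the calibration tests).

The encryption audit for a single region:

```r
bundle <- build_roi_bundle(cohort$volumes[[1]], cohort$masks[[1]])
security_report(bundle$roi3d$image, key)
#> <security_report> round-trip SSIM = 1 (bit-identical: TRUE)
#> # A tibble: 6 × 5
#>   image      direction         r n_pairs defined
#>   <chr>      <chr>         <dbl>   <int> <lgl>
#> 1 plaintext  horizontal  0.921      5000 TRUE
#> 2 plaintext  vertical    0.912      5000 TRUE
#> 3 plaintext  diagonal    0.854      5000 TRUE
#> 4 ciphertext horizontal  0.00851    5000 TRUE
#> 5 ciphertext vertical    0.0253     5000 TRUE
#> 6 ciphertext diagonal   -0.0207     5000 TRUE
```

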