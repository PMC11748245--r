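#' Run the full encrypted-radiomics pipeline on a synthetic cohort
#'
#' End-to-end driver used by the package's calibration and recovery
#' studies: generate (or accept) a cohort, split it with stratification on
#' the target, build per-patient ROI bundles, push every region through the
#' AES encrypt/decrypt round trip, extract features, fit the RadScore
#' cascade on the training split and evaluate on the held-out split.
#'
#' @param spec a [phantom_spec()] or an already generated
#'   `synthetic_cohort`.
#' @param target label to model (default `"EGFR"`).
#' @param cfg an [extraction_config()]; the calibration studies use
#'   `wavelet = FALSE` (108 original-image features per region) to keep
#'   problem sizes compact.
#' @param train_fraction stratified split fraction.
#' @param seed integer seed for the split and the selection cascade.
#' @param models build the five-model family via [build_all_models()]?
#'   When `FALSE` only the combined-cascade RadScore and its test AUC are
#'   computed (the fast path).
#' @param classifier a [classifier_spec()] for the model stage.
#' @param q,k cascade parameters.
#' @param B bootstrap replicates when `models = TRUE`.
#' @return a list with the fitted `radscore` model, `test_auc`,
#'   `screen_rejections` (count of MWU/BH-FDR-significant features on the
#'   training split), `n_features`, the train/test feature tables and —
#'   when `models = TRUE` — the `treatment_model_set`.
#' @export
run_pipeline <- function(spec, target = "EGFR", cfg = extraction_config(),
                         train_fraction = 0.6, seed = 1L, models = FALSE,
                         classifier = classifier_spec("logistic"),
                         q = 0.05, k = 30L, B = 500L) {
  cohort <- if (inherits(spec, "synthetic_cohort")) spec else generate_cohort(spec)
  key <- rad_key(paste(rep("5a", 32), collapse = ""))
  sp <- split_cohort(cohort, train_fraction, stratify_on = target, seed = seed)
  feats_tr <- extract_cohort(sp$train, cfg, key = key)
  feats_te <- extract_cohort(sp$test, cfg, key = key)
  y_tr <- sp$train$labels[[target]]
  y_te <- sp$test$labels[[target]]

  feat_cols <- setdiff(names(feats_tr), "patient_id")
  rs <- fit_radscore(feats_tr[, feat_cols, drop = FALSE], y_tr, q = q, k = k,
                     seed = seed, region = "combined")
  test_scores <- compute_radscore(rs, feats_te)
  out <- list(
    radscore = rs,
    test_auc = roc_auc(test_scores, y_te),
    train_auc = roc_auc(compute_radscore(rs, feats_tr), y_tr),
    screen_rejections = sum(rs$screening$survivor),
    n_features = length(feat_cols),
    test_scores = test_scores,
    train = list(features = feats_tr, clinical = sp$train$clinical,
                 labels = sp$train$labels),
    test = list(features = feats_te, clinical = sp$test$clinical,
                labels = sp$test$labels)
  )
  if (models) {
    out$model_set <- build_all_models(out$train, out$test, target,
                                      classifier = classifier, q = q, k = k,
                                      B = B, seed = seed)
  }
  out
}
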