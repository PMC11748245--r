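# Classifier registry and evaluation machinery.

.classifier_registry <- c("logistic", "svm_linear", "svm_rbf",
                          "random_forest", "gradient_boosting", "knn",
                          "naive_bayes")

default_grid <- function(algorithm) {
  switch(algorithm,
    logistic = list(list()),
    svm_linear = lapply(c(0.1, 1, 10), function(c) list(cost = c)),
    svm_rbf = unlist(lapply(c(0.5, 1, 5), function(c) {
      lapply(c(0.05, 0.2), function(g) list(cost = c, gamma = g))
    }), recursive = FALSE),
    random_forest = lapply(c(300), function(t) list(num.trees = t)),
    gradient_boosting = lapply(c(2, 3), function(d) {
      list(max_depth = d, nrounds = 50, eta = 0.3)
    }),
    knn = lapply(c(3, 5, 9, 15), function(k) list(k = k)),
    naive_bayes = list(list(laplace = 0)),
    abort(sprintf("unknown algorithm `%s`", algorithm))
  )
}

#' Classifier specification
#'
#' One of the package's seven-classifier registry (logistic regression,
#' linear SVM, RBF SVM, random forest, gradient boosting, k-nearest
#' neighbors, naive Bayes) plus a hyperparameter grid searched by
#' cross-validated AUC.
#'
#' @param algorithm registry tag.
#' @param grid list of named hyperparameter lists (default grid per
#'   algorithm); must be non-empty.
#' @param seed integer seed used for fold assignment and stochastic
#'   learners.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = "logistic", grid = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm, .classifier_registry)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (length(grid) == 0L) abort("hyperparameter grid must be non-empty")
  structure(list(algorithm = algorithm, grid = grid, seed = as.integer(seed)),
            class = "classifier_spec")
}

fit_one_classifier <- function(algorithm, params, X, y, seed = 1L) {
  y <- as.integer(y)
  df <- as.data.frame(X)
  fit <- switch(algorithm,
    logistic = suppressWarnings(glm(y ~ ., data = cbind(df, y = y),
                                    family = binomial())),
    svm_linear = e1071::svm(x = as.matrix(X), y = factor(y, levels = c(0, 1)),
                            kernel = "linear", cost = params$cost %||% 1,
                            probability = TRUE, scale = FALSE),
    svm_rbf = e1071::svm(x = as.matrix(X), y = factor(y, levels = c(0, 1)),
                         kernel = "radial", cost = params$cost %||% 1,
                         gamma = params$gamma %||% (1 / ncol(X)),
                         probability = TRUE, scale = FALSE),
    random_forest = ranger::ranger(
      x = df, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$num.trees %||% 300, seed = seed,
      num.threads = 1
    ),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3,
                    eta = params$eta %||% 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1),
      nrounds = params$nrounds %||% 50, verbose = 0
    ),
    knn = list(train = as.matrix(X), y = factor(y, levels = c(0, 1)),
               k = params$k %||% 5),
    naive_bayes = e1071::naiveBayes(df, factor(y, levels = c(0, 1)),
                                    laplace = params$laplace %||% 0)
  )
  structure(list(algorithm = algorithm, params = params, fit = fit,
                 features = colnames(df)),
            class = "encrad_classifier")
}

#' @export
predict.encrad_classifier <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  df <- as.data.frame(X)
  switch(object$algorithm,
    logistic = as.numeric(predict(object$fit, df, type = "response")),
    svm_linear = ,
    svm_rbf = {
      pr <- predict(object$fit, X, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    random_forest = as.numeric(predict(object$fit, df)$predictions[, "1"]),
    gradient_boosting = as.numeric(
      predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1))
    ),
    knn = {
      pred <- class::knn(object$fit$train, X, object$fit$y, k = object$fit$k,
                         prob = TRUE)
      p <- attr(pred, "prob")
      as.numeric(ifelse(pred == "1", p, 1 - p))
    },
    naive_bayes = as.numeric(predict(object$fit, df, type = "raw")[, "1"])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a classifier with 5-fold cross-validated grid search
#'
#' Every grid point is scored by mean stratified-CV AUC; the best point is
#' refit on the full training data. Stratification guarantees both classes
#' in each training fold (an error is raised when impossible).
#'
#' @param spec a [classifier_spec()].
#' @param table data frame / matrix of predictors.
#' @param labels binary labels.
#' @param cv_folds folds of the grid search (default 5).
#' @return An object of class `encrad_model` with the chosen `params`,
#'   the refit classifier and the grid-search table.
#' @export
fit_model <- function(spec, table, labels, cv_folds = 5L) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(labels)
  if (min(tabulate(y + 1L, 2L)) < 2L) {
    abort("cannot stratify: a class has < 2 members")
  }
  X <- as.data.frame(table)
  fold <- stratified_folds(y, cv_folds, spec$seed)
  cv_auc <- vapply(seq_along(spec$grid), function(gi) {
    aucs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
        return(NA_real_)
      }
      m <- fit_one_classifier(spec$algorithm, spec$grid[[gi]],
                              X[tr, , drop = FALSE], y[tr], seed = spec$seed)
      roc_auc(predict(m, X[!tr, , drop = FALSE]), y[!tr])
    }, 1.0)
    mean(aucs, na.rm = TRUE)
  }, 1.0)
  best <- which.max(cv_auc)
  final <- fit_one_classifier(spec$algorithm, spec$grid[[best]], X, y,
                              seed = spec$seed)
  structure(
    list(spec = spec, params = spec$grid[[best]], classifier = final,
         grid_auc = cv_auc, features = colnames(X)),
    class = "encrad_model"
  )
}

#' @export
predict.encrad_model <- function(object, newdata, ...) {
  predict(object$classifier, newdata)
}

#' Repeated stratified cross-validation
#'
#' `repeats` independent stratified `folds`-fold partitions; within each
#' repeat the classifier is trained on the out-of-fold data and scored by
#' test-fold AUC, producing `repeats * folds` fold-level AUCs. Every sample
#' appears in a test fold exactly `repeats` times.
#'
#' @param spec a [classifier_spec()] (its first grid point is used).
#' @param table predictors.
#' @param labels binary labels.
#' @param repeats,folds repetition structure (default 30 x 5).
#' @param seed integer seed.
#' @return a tibble with columns `repeat_id`, `fold`, `auc`; the per-sample
#'   test-appearance counts are in `attr(, "appearances")`.
#' @export
repeated_cv <- function(spec, table, labels, repeats = 30L, folds = 5L,
                        seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(labels)
  X <- as.data.frame(table)
  appearances <- integer(length(y))
  seeds <- derive_seeds(seed, repeats)
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, folds, seeds[r])
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_one_classifier(spec$algorithm, spec$grid[[1]],
                              X[tr, , drop = FALSE], y[tr], seed = seeds[r])
      roc_auc(predict(m, X[!tr, , drop = FALSE]), y[!tr])
    }, 1.0)
    appearances <- appearances + 1L
    out[[r]] <- tibble(repeat_id = r, fold = seq_len(folds), auc = aucs)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "appearances") <- appearances * 1L
  res
}

#' Backward AIC selection of clinical covariates
#'
#' Backward stepwise logistic regression minimizing
#' `AIC = 2k - 2 log L`, starting from all covariates; deterministic given
#' the column order.
#'
#' @param clinical data frame of clinical covariates (factors or numerics;
#'   character columns are converted to factors).
#' @param labels binary labels.
#' @return a list with `retained` (term labels), `fit` (the final glm) and
#'   `aic`.
#' @export
aic_select_clinical <- function(clinical, labels) {
  df <- as.data.frame(clinical)
  df[] <- lapply(df, function(col) if (is.character(col)) factor(col) else col)
  df$.y <- as.integer(labels)
  full <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  red <- suppressWarnings(step(full, direction = "backward", trace = 0))
  list(retained = attr(stats::terms(red), "term.labels"), fit = red,
       aic = stats::AIC(red))
}

#' Evaluate probability predictions on a held-out test set
#'
#' AUC with percentile-bootstrap CI, accuracy / sensitivity / specificity
#' at the Youden-optimal threshold determined on the *training*
#' predictions, and the decision curve.
#'
#' @param train_probs,train_labels training-set predictions and labels
#'   (used only to fix the operating threshold).
#' @param test_probs,test_labels held-out predictions and labels.
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @param model_name stored tag.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(train_probs, train_labels, test_probs,
                                 test_labels, B = 1000L, seed = 1L,
                                 model_name = "model") {
  ci <- bootstrap_ci(test_probs, test_labels, B = B, seed = seed)
  thr <- youden_threshold(train_probs, train_labels)
  cm <- classification_metrics(test_probs, test_labels, thr)
  structure(
    list(
      model = model_name,
      auc = ci$auc, ci_lower = ci$lower, ci_upper = ci$upper,
      threshold = thr,
      accuracy = cm$accuracy, sensitivity = cm$sensitivity,
      specificity = cm$specificity,
      dca = decision_curve(test_probs, test_labels),
      test_probs = test_probs, test_labels = as.integer(test_labels)
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %s: AUC %.3f (95%% CI %.3f-%.3f), acc %.3f, sens %.3f, spec %.3f\n",
    x$model, x$auc, x$ci_lower, x$ci_upper, x$accuracy, x$sensitivity,
    x$specificity
  ))
  invisible(x)
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(model = x$model, auc = x$auc, ci_lower = x$ci_lower,
         ci_upper = x$ci_upper, accuracy = x$accuracy,
         sensitivity = x$sensitivity, specificity = x$specificity)
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  y <- object$test_labels
  s <- object$test_probs
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE))
  roc <- tibble(
    fpr = vapply(cuts, function(ct) mean(s[y == 0] >= ct), 1.0),
    tpr = vapply(cuts, function(ct) mean(s[y == 1] >= ct), 1.0)
  )
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = 2, color = "grey") +
    ggplot2::labs(
      title = sprintf("%s (AUC %.3f)", object$model, object$auc),
      x = "1 - specificity", y = "sensitivity"
    ) +
    ggplot2::theme_minimal()
}

#' Serialize / restore an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path JSON file path.
#' @return the path (writer, invisibly) or the restored report (reader).
#' @export
report_to_json <- function(report, path) {
  obj <- unclass(report)
  obj$dca <- as.data.frame(report$dca)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$dca <- structure(as_tibble(obj$dca),
                       class = c("decision_curve", class(tibble())))
  structure(obj, class = "evaluation_report")
}

#' Build and evaluate the five model families for one target
#'
#' The full modeling stage for one therapy-response label: a clinical model
#' on backward-AIC-selected covariates, three regional radiomics models
#' (each using that region's RadScore as sole predictor), and the combined
#' radiomics-clinical model (AIC-retained covariates plus the RadScore
#' fitted on the pooled three-region feature table). Each model is trained
#' on the training split only and evaluated on the held-out test split;
#' DeLong tests compare every model against the combined one.
#'
#' @param train,test lists with elements `features` (wide table from
#'   [extract_cohort()]), `clinical`, `labels`.
#' @param target label column name.
#' @param classifier a [classifier_spec()] applied to the predictor sets.
#' @param q,k RadScore cascade parameters (see [fit_radscore()]).
#' @param B bootstrap replicates for the CIs.
#' @param seed integer seed.
#' @return An object of class `treatment_model_set`: per-model
#'   `evaluation_report`s, the fitted `radscore` models and a `delong`
#'   tibble.
#' @export
build_all_models <- function(train, test, target,
                             classifier = classifier_spec("logistic"),
                             q = 0.05, k = 30L, B = 500L, seed = 1L) {
  y_tr <- train$labels[[target]]
  y_te <- test$labels[[target]]
  if (is.null(y_tr) || is.null(y_te)) abort(sprintf("no label `%s`", target))
  feat_cols <- setdiff(names(train$features), "patient_id")
  region_of <- sub("_.*$", "", feat_cols)

  clin_tr <- anonymize_clinical(train$clinical)
  clin_te <- anonymize_clinical(test$clinical)
  clin_tr <- clin_tr[, setdiff(names(clin_tr), c("EGFR", "Del19", "L858R", "T790M", "PDL1"))]
  clin_te <- clin_te[, names(clin_tr)]
  aic <- aic_select_clinical(clin_tr, y_tr)

  # dummy-encode train and test jointly so factor levels stay aligned
  design_pair <- function(tr, te, retained) {
    if (!length(retained)) {
      return(list(train = data.frame(intercept_only = rep(1, nrow(tr))),
                  test = data.frame(intercept_only = rep(1, nrow(te)))))
    }
    df <- rbind(as.data.frame(tr)[, retained, drop = FALSE],
                as.data.frame(te)[, retained, drop = FALSE])
    df[] <- lapply(df, function(col) if (is.character(col)) factor(col) else col)
    mm <- stats::model.matrix(~ ., df)[, -1, drop = FALSE]
    colnames(mm) <- make.names(colnames(mm))
    list(train = as.data.frame(mm[seq_len(nrow(tr)), , drop = FALSE]),
         test = as.data.frame(mm[nrow(tr) + seq_len(nrow(te)), , drop = FALSE]))
  }

  models <- list()
  radscores <- list()
  scores_tr <- list()
  scores_te <- list()

  # clinical model
  dp <- design_pair(clin_tr, clin_te, aic$retained)
  Xtr <- dp$train
  Xte <- dp$test
  m <- fit_model(classifier, Xtr, y_tr)
  scores_tr$clinical <- predict(m, Xtr)
  scores_te$clinical <- predict(m, Xte)
  models$clinical <- m

  # regional radiomics models
  region_tag <- c(roi2d = "2D", roi3d = "3D", peritumoral = "peritumoral")
  for (region in names(region_tag)) {
    cols <- feat_cols[region_of == region]
    rs <- fit_radscore(train$features[, cols, drop = FALSE], y_tr, q = q,
                       k = k, seed = seed, region = region_tag[[region]])
    radscores[[region]] <- rs
    str_ <- compute_radscore(rs, train$features)
    ste <- compute_radscore(rs, test$features)
    Xr_tr <- data.frame(radscore = str_)
    Xr_te <- data.frame(radscore = ste)
    m <- fit_model(classifier, Xr_tr, y_tr)
    scores_tr[[region]] <- predict(m, Xr_tr)
    scores_te[[region]] <- predict(m, Xr_te)
    models[[region]] <- m
  }

  # combined radiomics-clinical model: pooled-feature RadScore + covariates
  rs_comb <- fit_radscore(train$features[, feat_cols, drop = FALSE], y_tr,
                          q = q, k = k, seed = seed, region = "combined")
  radscores$combined <- rs_comb
  Xc_tr <- dp$train
  Xc_te <- dp$test
  Xc_tr$radscore <- compute_radscore(rs_comb, train$features)
  Xc_te$radscore <- compute_radscore(rs_comb, test$features)
  m <- fit_model(classifier, Xc_tr, y_tr)
  scores_tr$combined <- predict(m, Xc_tr)
  scores_te$combined <- predict(m, Xc_te)
  models$combined <- m

  nm <- c("clinical", "roi2d", "roi3d", "peritumoral", "combined")
  reports <- lapply(nm, function(i) {
    evaluate_predictions(scores_tr[[i]], y_tr, scores_te[[i]], y_te, B = B,
                         seed = seed, model_name = i)
  })
  names(reports) <- nm
  delong <- dplyr::bind_rows(lapply(setdiff(nm, "combined"), function(i) {
    dl <- delong_test(scores_te$combined, scores_te[[i]], y_te)
    tibble(model_a = "combined", model_b = i, auc_a = dl$auc_a,
           auc_b = dl$auc_b, z = dl$z, p = dl$p)
  }))
  structure(
    list(target = target, reports = reports, models = models,
         radscores = radscores, aic_retained = aic$retained,
         delong = delong, test_scores = scores_te,
         test_labels = as.integer(y_te)),
    class = "treatment_model_set"
  )
}

#' @export
tidy.treatment_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x$reports, glance)) %>%
    mutate(target = x$target, .before = 1)
}

#' @export
print.treatment_model_set <- function(x, ...) {
  cat(sprintf("<treatment_model_set> target %s\n", x$target))
  print(tidy(x))
  invisible(x)
}
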