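#' Train-set Z-score normalization
#'
#' Estimates per-feature mean and standard deviation on the training table
#' only; test data are transformed with the training parameters (never
#' their own), so no information leaks across the split. Constant features
#' (zero training SD) are flagged and dropped on application, with a
#' warning.
#'
#' @param train a data frame of numeric feature columns (non-numeric
#'   columns such as `patient_id` are carried through untouched).
#' @return An object of class `normalization_params`.
#' @export
fit_normalizer <- function(train) {
  num <- vapply(train, is.numeric, TRUE)
  feats <- names(train)[num]
  mu <- vapply(train[feats], mean, 1.0)
  sdev <- vapply(train[feats], sd, 1.0)
  structure(
    list(feature = feats, mean = mu, sd = sdev,
         constant = feats[sdev == 0 | !is.finite(sdev)]),
    class = "normalization_params"
  )
}

#' @rdname fit_normalizer
#' @param params a `normalization_params` fitted on the training set.
#' @param table a data frame to transform.
#' @return `apply_normalizer` returns the transformed tibble with constant
#'   training features removed.
#' @export
apply_normalizer <- function(params, table) {
  stopifnot(inherits(params, "normalization_params"))
  keep <- setdiff(params$feature, params$constant)
  missing <- setdiff(keep, names(table))
  if (length(missing)) {
    abort(sprintf("table lacks %d features seen at fit time (e.g. %s)",
                  length(missing), missing[1]))
  }
  if (length(params$constant)) {
    warn(sprintf("dropping %d constant training feature(s)",
                 length(params$constant)))
  }
  out <- as_tibble(table)
  for (f in keep) out[[f]] <- (out[[f]] - params$mean[f]) / params$sd[f]
  out[, c(setdiff(names(table), params$feature), keep), drop = FALSE]
}

#' Mann-Whitney U screen with Benjamini-Hochberg FDR
#'
#' Two-sided Mann-Whitney U test of each feature against the binary label
#' (exact when both groups have at most 8 observations, otherwise the
#' normal approximation with tie correction), followed by Benjamini-
#' Hochberg step-up adjustment; survivors are the features significant at
#' the FDR level `q`.
#'
#' @param table data frame of numeric features.
#' @param labels binary vector (0/1), both classes non-empty.
#' @param q FDR level (default 0.05).
#' @return a list with a `results` tibble (`feature`, `p`, `q_value`,
#'   `survivor`) and `survivors` (character vector).
#' @export
mwu_fdr_filter <- function(table, labels, q = 0.05) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) abort("labels contain a single class")
  num <- vapply(table, is.numeric, TRUE)
  feats <- names(table)[num]
  g1 <- labels == 1L
  exact <- sum(g1) <= 8L && sum(!g1) <= 8L
  p <- vapply(feats, function(f) {
    x <- table[[f]]
    suppressWarnings(
      wilcox.test(x[g1], x[!g1], exact = exact, correct = FALSE)$p.value
    )
  }, 1.0)
  p[!is.finite(p)] <- 1
  qv <- p.adjust(p, method = "BH")
  res <- tibble(feature = feats, p = unname(p), q_value = unname(qv),
                survivor = unname(qv < q))
  list(results = res, survivors = res$feature[res$survivor])
}

# one-hot indicators of quantile-discretized columns (4 bins, unique breaks)
.quantize4 <- function(x, bins = 4L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  cut(x, br, include.lowest = TRUE, labels = FALSE)
}

.mi_from_joint <- function(J) {
  n <- sum(J)
  P <- J / n
  px <- rowSums(P)
  py <- colSums(P)
  pos <- P > 0
  sum(P[pos] * log(P[pos] / (px[row(P)][pos] * py[col(P)][pos])))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward selection with the mutual-information difference (MID)
#' score: at each step pick the feature maximizing
#' `I(f; y) - mean I(f; selected)`. Mutual information uses 4-quantile
#' discretization of continuous features (scale-free and deterministic);
#' ties break on the earlier column.
#'
#' @param table data frame of numeric features.
#' @param labels binary labels.
#' @param k number of features to retain (capped at the available count,
#'   with a warning when fewer are available).
#' @return character vector of the `k` selected features in rank order.
#' @export
mrmr_select <- function(table, labels, k = 30L) {
  num <- vapply(table, is.numeric, TRUE)
  feats <- names(table)[num]
  if (k > length(feats)) {
    warn(sprintf("k = %d exceeds the %d available features; returning all",
                 k, length(feats)))
    k <- length(feats)
  }
  y <- as.integer(labels)
  Q <- vapply(feats, function(f) .quantize4(table[[f]]), integer(length(y)))
  relevance <- vapply(seq_along(feats), function(j) {
    .mi_from_joint(base::table(Q[, j], y))
  }, 1.0)
  mi_cache <- matrix(NA_real_, length(feats), length(feats))
  pair_mi <- function(a, b) {
    if (is.na(mi_cache[a, b])) {
      m <- .mi_from_joint(base::table(Q[, a], Q[, b]))
      mi_cache[a, b] <<- m
      mi_cache[b, a] <<- m
    }
    mi_cache[a, b]
  }
  selected <- integer(0)
  remaining <- seq_along(feats)
  for (step in seq_len(k)) {
    score <- vapply(remaining, function(j) {
      red <- if (length(selected)) {
        mean(vapply(selected, function(s) pair_mi(j, s), 1.0))
      } else {
        0
      }
      relevance[j] - red
    }, 1.0)
    best <- remaining[which.max(score)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  feats[selected]
}

# stratified fold assignment (every fold gets both classes when possible)
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample(folds), length(idx))
    }
    fold
  })
}

#' LASSO feature selection with misclassification-error CV
#'
#' L1-penalized logistic regression over a 50-value log-spaced lambda grid
#' (from the data-derived maximal lambda down to 1e-3 of it). The penalty
#' is chosen by stratified 5-fold cross-validation minimizing the mean
#' misclassification error (MCE); ties go to the larger (sparser) lambda.
#' The final model is refit on the full training table at the chosen
#' lambda. A fold degenerating to a single class triggers up to 3 refolds
#' with fresh seeds before erroring.
#'
#' @param table data frame of numeric features (already normalized).
#' @param labels binary labels.
#' @param lambda_grid optional decreasing lambda sequence.
#' @param cv_folds number of folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return a list of class `lasso_selection`: `lambda`, `coefficients`
#'   (named, nonzero only), `intercept`, `cv` tibble (`lambda`, `mce`),
#'   `features` (nonzero-coefficient names), `fit` (the glmnet object).
#' @export
lasso_select <- function(table, labels, lambda_grid = NULL, cv_folds = 5L,
                         seed = 1L) {
  y <- as.integer(labels)
  num <- vapply(table, is.numeric, TRUE)
  X <- as.matrix(table[, num, drop = FALSE])
  if (length(unique(y)) < 2L) abort("labels contain a single class")
  # glmnet requires >= 2 columns; a zero column is inert (coefficient 0)
  if (ncol(X) == 1L) X <- cbind(X, .zero.pad. = 0)
  if (is.null(lambda_grid)) {
    # glmnet's own path construction, fixed at 50 values down to 1e-3 ratio
    path <- glmnet::glmnet(X, y, family = "binomial", nlambda = 50,
                           lambda.min.ratio = 1e-3)
    lambda_grid <- path$lambda
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  mce <- NULL
  for (attempt in seq_len(3L)) {
    fold <- stratified_folds(y, cv_folds, seed + (attempt - 1L) * 1000L)
    ok <- all(vapply(seq_len(cv_folds), function(f) {
      length(unique(y[fold != f])) == 2L
    }, TRUE))
    if (!ok) next
    errs <- matrix(NA_real_, cv_folds, length(lambda_grid))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                            lambda = lambda_grid)
      pr <- predict(fit, X[!tr, , drop = FALSE], type = "response",
                    s = lambda_grid)
      errs[f, ] <- colMeans((pr > 0.5) != y[!tr])
    }
    mce <- colMeans(errs)
    break
  }
  if (is.null(mce)) abort("could not build folds with both classes after 3 attempts")
  best <- which(mce == min(mce))[1] # grid is decreasing: first = largest lambda
  lambda <- lambda_grid[best]
  fit <- glmnet::glmnet(X, y, family = "binomial", lambda = lambda_grid)
  cf <- as.numeric(coef(fit, s = lambda))
  names(cf) <- rownames(coef(fit, s = lambda))
  cf <- cf[names(cf) != ".zero.pad."]
  nz <- cf[-1][cf[-1] != 0]
  structure(
    list(lambda = lambda, coefficients = nz, intercept = cf[1],
         cv = tibble(lambda = lambda_grid, mce = mce),
         features = names(nz), fit = fit),
    class = "lasso_selection"
  )
}

#' Fit a RadScore model (the full three-step cascade)
#'
#' Z-score normalization (training parameters), Mann-Whitney U + BH-FDR
#' screening, mRMR redundancy reduction and cross-validated LASSO, yielding
#' the radiomics score: `RadScore = intercept + sum(coef_j * z_j)` over the
#' selected normalized features. Selection containment holds by
#' construction: nonzero-coefficient features are a subset of the mRMR set,
#' itself a subset of the FDR survivors.
#'
#' @param train data frame of numeric feature columns (training set only).
#' @param labels binary training labels.
#' @param q FDR level of the screening step.
#' @param k mRMR retention count (default 30).
#' @param cv_folds,seed forwarded to [lasso_select()].
#' @param region scope tag stored on the model (`"2D"`, `"3D"`,
#'   `"peritumoral"`, `"combined"`).
#' @return An object of class `radscore_model`.
#' @export
fit_radscore <- function(train, labels, q = 0.05, k = 30L, cv_folds = 5L,
                         seed = 1L, region = "combined") {
  norm <- fit_normalizer(train)
  z <- suppressWarnings(apply_normalizer(norm, train))
  num <- names(z)[vapply(z, is.numeric, TRUE)]
  z <- z[, num, drop = FALSE]
  screen <- mwu_fdr_filter(z, labels, q = q)
  surv <- screen$survivors
  if (length(surv) == 0L) {
    model <- structure(
      list(features = character(0), coefficients = numeric(0),
           intercept = 0, normalization = norm, region = region,
           screening = screen$results, mrmr = character(0), lasso = NULL,
           train_scores = rep(0, length(labels))),
      class = "radscore_model"
    )
    return(model)
  }
  ranked <- suppressWarnings(
    mrmr_select(z[, surv, drop = FALSE], labels, k = min(k, length(surv)))
  )
  las <- lasso_select(z[, ranked, drop = FALSE], labels, cv_folds = cv_folds,
                      seed = seed)
  model <- structure(
    list(features = las$features, coefficients = las$coefficients,
         intercept = unname(las$intercept), normalization = norm,
         region = region, screening = screen$results, mrmr = ranked,
         lasso = las, train_scores = NULL),
    class = "radscore_model"
  )
  model$train_scores <- compute_radscore(model, train)
  model
}

#' Compute RadScores for a feature table
#'
#' Applies the model's stored training normalization and linear
#' coefficients: a pure function of the input rows.
#'
#' @param model a `radscore_model`.
#' @param table data frame holding (at least) the model's features on the
#'   original scale.
#' @return numeric vector of per-patient scores.
#' @export
compute_radscore <- function(model, table) {
  stopifnot(inherits(model, "radscore_model"))
  if (length(model$features) == 0L) {
    return(rep(model$intercept, nrow(table)))
  }
  z <- suppressWarnings(apply_normalizer(model$normalization, table))
  zm <- as.matrix(z[, model$features, drop = FALSE])
  as.numeric(model$intercept + zm %*% model$coefficients)
}

#' @export
print.radscore_model <- function(x, ...) {
  cat(sprintf(
    "<radscore_model> region %s: %d selected features (lambda = %s)\n",
    x$region, length(x$features),
    if (is.null(x$lasso)) "NA" else signif(x$lasso$lambda, 4)
  ))
  if (length(x$features)) {
    print(tibble(feature = x$features, coefficient = unname(x$coefficients)))
  }
  invisible(x)
}

#' @export
tidy.radscore_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", x$features),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.radscore_model <- function(x, ...) {
  tibble(
    region = x$region,
    n_screened = sum(x$screening$survivor),
    n_mrmr = length(x$mrmr),
    n_selected = length(x$features),
    lambda = if (is.null(x$lasso)) NA_real_ else x$lasso$lambda
  )
}

#' Serialize / restore a RadScore model as JSON
#'
#' @param model a `radscore_model`.
#' @param path JSON file path.
#' @return `radscore_to_json` returns `path` invisibly;
#'   `radscore_from_json` the restored model (sufficient for
#'   [compute_radscore()]; the internal glmnet fit is not persisted).
#' @export
radscore_to_json <- function(model, path) {
  stopifnot(inherits(model, "radscore_model"))
  keep <- setdiff(model$normalization$feature, model$normalization$constant)
  obj <- list(
    region = model$region,
    features = model$features,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    normalization = list(
      feature = keep,
      mean = as.list(model$normalization$mean[keep]),
      sd = as.list(model$normalization$sd[keep])
    ),
    lambda = if (is.null(model$lasso)) NULL else model$lasso$lambda
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname radscore_to_json
#' @export
radscore_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  norm <- structure(
    list(feature = obj$normalization$feature,
         mean = unlist(obj$normalization$mean),
         sd = unlist(obj$normalization$sd),
         constant = character(0)),
    class = "normalization_params"
  )
  structure(
    list(features = obj$features, coefficients = unlist(obj$coefficients),
         intercept = obj$intercept, normalization = norm,
         region = obj$region, screening = NULL, mrmr = NULL, lasso = NULL,
         train_scores = NULL),
    class = "radscore_model"
  )
}
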