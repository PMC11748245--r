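test_that("AIC value matches the 2k - 2logL formula on a hand fit", {
  df <- data.frame(x = c(0, 1, 2, 3), y = c(0, 0, 1, 1))
  fit <- suppressWarnings(glm(y ~ x, data = df, family = binomial()))
  ll <- sum(df$y * log(fitted(fit)) + (1 - df$y) * log(1 - fitted(fit)))
  expect_equal(stats::AIC(fit), 2 * 2 - 2 * ll, tolerance = 1e-8)
})

test_that("backward AIC selection: null behavior and power", {
  # pure-noise covariates collapse to the intercept-only model in most
  # seeds: each noise covariate survives backward AIC with probability
  # P(chisq_1 > 2) ~ 0.157, so two covariates give ~71% intercept-only
  null_hits <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 400
    clin <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- rbinom(n, 1, 0.4)
    sel <- aic_select_clinical(clin, y)
    if (length(sel$retained) == 0) null_hits <- null_hits + 1L
  }
  expect_gte(null_hits, 12L)

  # a strong covariate (OR = 3) is retained nearly always
  power_hits <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    n <- 400
    clin <- data.frame(strong = rnorm(n), junk = rnorm(n))
    y <- rbinom(n, 1, plogis(-0.3 + log(3) * clin$strong))
    sel <- aic_select_clinical(clin, y)
    if ("strong" %in% sel$retained) power_hits <- power_hits + 1L
  }
  expect_gte(power_hits, 18L) # >= 90%
})

test_that("every registry algorithm fits separable data perfectly", {
  set.seed(19)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- data.frame(u = y * 4 + runif(n), v = rnorm(n))
  for (alg in encrad:::.classifier_registry) {
    spec <- classifier_spec(alg, seed = 3)
    m <- suppressWarnings(fit_model(spec, X, y))
    expect_true(list(m$params) %in% list(spec$grid) ||
                  any(vapply(spec$grid, identical, TRUE, y = m$params)))
    auc <- roc_auc(suppressWarnings(predict(m, X)), y)
    expect_equal(auc, 1, tolerance = 1e-9)
  }
  # determinism: the same seed picks the same grid point
  spec <- classifier_spec("knn", seed = 5)
  m1 <- fit_model(spec, X, y)
  m2 <- fit_model(spec, X, y)
  expect_identical(m1$params, m2$params)
})

test_that("repeated stratified CV has the exact 30 x 5 structure", {
  set.seed(20)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- data.frame(x1 = rnorm(n) + 0.5 * y, x2 = rnorm(n))
  cv <- repeated_cv(classifier_spec("logistic"), X, y, repeats = 30,
                    folds = 5, seed = 9)
  expect_identical(nrow(cv), 150L)
  expect_true(all(attr(cv, "appearances") == 30L))
  expect_identical(sort(unique(cv$repeat_id)), 1:30)
})

test_that("repeated CV is calibrated under label permutation", {
  set.seed(22)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  cv <- repeated_cv(classifier_spec("logistic"), X, sample(y), repeats = 10,
                    folds = 5, seed = 4)
  expect_gt(mean(cv$auc), 0.40)
  expect_lt(mean(cv$auc), 0.60)
})

test_that("the five model families assemble and evaluate per target", {
  cfg <- extraction_config(wavelet = FALSE)
  co <- generate_cohort(phantom_spec(
    n_patients = 150, rng_seed = 555,
    intratumoral_texture_shift = c(EGFR = 1, PDL1 = 0.5),
    clinical_effect = c(EGFR = 0.6)
  ))
  sp <- split_cohort(co, 0.6, "EGFR", seed = 1)
  key <- fixed_key()
  train <- list(features = extract_cohort(sp$train, cfg, key = key),
                clinical = sp$train$clinical, labels = sp$train$labels)
  test <- list(features = extract_cohort(sp$test, cfg, key = key),
               clinical = sp$test$clinical, labels = sp$test$labels)
  for (target in c("EGFR", "PDL1")) {
    ms <- build_all_models(train, test, target, B = 100, seed = 2)
    expect_named(ms$reports,
                 c("clinical", "roi2d", "roi3d", "peritumoral", "combined"))
    g <- tidy(ms)
    expect_identical(nrow(g), 5L)
    expect_true(all(g$auc >= 0 & g$auc <= 1))
    expect_identical(nrow(ms$delong), 4L)
    # regional RadScore models carry their scope tags
    expect_identical(ms$radscores$roi3d$region, "3D")
    expect_identical(ms$radscores$combined$region, "combined")
    # reports survive a JSON round trip
    path <- tempfile(fileext = ".json")
    report_to_json(ms$reports$combined, path)
    expect_equal(report_from_json(path)$auc, ms$reports$combined$auc,
                 tolerance = 1e-12)
    unlink(path)
  }
})

test_that("evaluation reports serialize and reload losslessly", {
  set.seed(23)
  y_tr <- rbinom(80, 1, 0.5)
  p_tr <- plogis(rnorm(80) + y_tr)
  y_te <- rbinom(60, 1, 0.5)
  p_te <- plogis(rnorm(60) + y_te)
  rep <- evaluate_predictions(p_tr, y_tr, p_te, y_te, B = 200, seed = 1,
                              model_name = "toy")
  expect_gte(rep$auc, rep$ci_lower - 1e-12)
  expect_lte(rep$auc, rep$ci_upper + 1e-12)
  path <- tempfile(fileext = ".json")
  report_to_json(rep, path)
  back <- report_from_json(path)
  expect_equal(back$auc, rep$auc, tolerance = 1e-12)
  expect_equal(back$dca$net_benefit, rep$dca$net_benefit, tolerance = 1e-12)
  expect_identical(back$model, "toy")
  unlink(path)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(glance(rep), "tbl_df")
})
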