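make_feature_toy <- function(n = 60, m = 8, seed = 1, effect = 0) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- as.data.frame(matrix(rnorm(n * m), n, m))
  names(X) <- paste0("f", seq_len(m))
  X$f1 <- X$f1 + effect * y
  list(X = tibble::as_tibble(X), y = y)
}

test_that("Z-score normalization uses training parameters only", {
  toy <- make_feature_toy(n = 50, m = 4, seed = 2)
  norm <- fit_normalizer(toy$X)
  z <- apply_normalizer(norm, toy$X)
  expect_true(all(abs(vapply(z, mean, 1.0)) < 1e-9))
  expect_true(all(abs(vapply(z, sd, 1.0) - 1) < 1e-9))
  # a shifted test table transformed with train params is NOT standard normal
  test_tbl <- toy$X
  test_tbl$f1 <- test_tbl$f1 + 5
  zt <- apply_normalizer(norm, test_tbl)
  expect_gt(abs(mean(zt$f1)), 3)
  expect_false(isTRUE(all.equal(zt$f1, as.numeric(scale(test_tbl$f1)))))
})

test_that("constant training features are flagged and dropped", {
  toy <- make_feature_toy(n = 30, m = 3, seed = 3)
  toy$X$f2 <- 7
  norm <- fit_normalizer(toy$X)
  expect_identical(norm$constant, "f2")
  expect_warning(z <- apply_normalizer(norm, toy$X), "constant")
  expect_false("f2" %in% names(z))
})

test_that("BH step-up reproduces the hand-worked rejection set", {
  # p = {0.001, 0.02, 0.03, 0.9} at q = 0.05: thresholds k*q/m =
  # {0.0125, 0.025, 0.0375, 0.05}; largest k with p(k) <= k q/m is 3
  p <- c(0.001, 0.02, 0.03, 0.9)
  q <- p.adjust(p, "BH")
  expect_identical(q < 0.05, c(TRUE, TRUE, TRUE, FALSE))
  # the same decision through the package screen
  set.seed(4)
  n <- 2000
  y <- rep(0:1, each = n / 2)
  X <- tibble::tibble(
    a = rnorm(n) + 0.4 * y, b = rnorm(n) + 0.25 * y,
    c = rnorm(n) + 0.2 * y, d = rnorm(n)
  )
  res <- mwu_fdr_filter(X, y, q = 0.05)
  expect_true(all(c("a", "b", "c") %in% res$survivors))
  expect_false("d" %in% res$survivors)
})

test_that("Mann-Whitney exact small-sample p matches enumeration", {
  # x = {1,2}, y = {3,4}: U = 0; 2 of the 6 arrangements are as extreme
  X <- tibble::tibble(f = c(1, 2, 3, 4))
  res <- mwu_fdr_filter(X, c(1, 1, 0, 0))
  expect_equal(res$results$p, 1 / 3, tolerance = 1e-12)
  expect_error(mwu_fdr_filter(X, c(1, 1, 1, 1)), "single class")
})

test_that("screen calibrates under label permutation", {
  set.seed(5)
  n <- 40
  m <- 60
  X <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * m), n, m)))
  names(X) <- paste0("f", 1:m)
  y <- rep(0:1, each = n / 2)
  fracs <- vapply(1:50, function(r) {
    yp <- sample(y)
    length(mwu_fdr_filter(X, yp, q = 0.05)$survivors) / m
  }, 1.0)
  expect_lte(mean(fracs), 0.05 + 3 * sqrt(0.05 / m))
})

test_that("mRMR ranks relevance first and penalizes redundancy", {
  set.seed(6)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- tibble::tibble(
    noise1 = rnorm(n),
    target_copy = as.numeric(y),
    noise2 = rnorm(n)
  )
  expect_identical(mrmr_select(X, y, k = 1), "target_copy")
  # an exact duplicate of the top feature ranks last among 3 candidates
  X2 <- tibble::tibble(
    strong = rnorm(n) + 2 * y,
    dup = NA_real_,
    weak = rnorm(n) + 0.8 * y
  )
  X2$dup <- X2$strong
  rk <- mrmr_select(X2, y, k = 3)
  expect_identical(rk[1], "strong")
  expect_identical(rk[3], "dup")
  expect_warning(mrmr_select(X2, y, k = 10), "exceeds")
})

test_that("LASSO selection: penalty limits and sparsity recovery", {
  toy <- make_feature_toy(n = 120, m = 6, seed = 7, effect = 2.5)
  las <- lasso_select(toy$X, toy$y, lambda_grid = c(100), seed = 1)
  expect_length(las$features, 0) # huge penalty kills every coefficient
  # single strong feature vs orthogonal noise: majority of seeds keep f1 only
  hits <- 0L
  clean <- 0L
  for (s in 1:20) {
    toy2 <- make_feature_toy(n = 120, m = 6, seed = 100 + s, effect = 2.5)
    l2 <- lasso_select(toy2$X, toy2$y, seed = s)
    if ("f1" %in% l2$features) hits <- hits + 1L
    if (!any(paste0("f", 3:6) %in% l2$features)) clean <- clean + 1L
  }
  expect_gte(hits, 18L)
  expect_gte(clean, 11L)
})

test_that("unpenalized limit approaches the plain logistic fit", {
  toy <- make_feature_toy(n = 400, m = 3, seed = 8, effect = 0.8)
  las <- lasso_select(toy$X, toy$y, lambda_grid = c(1e-8), seed = 1)
  ref <- glm(toy$y ~ ., data = as.data.frame(toy$X), family = binomial())
  expect_equal(unname(las$intercept), unname(coef(ref)[1]), tolerance = 1e-3)
  for (f in names(las$coefficients)) {
    expect_equal(unname(las$coefficients[f]), unname(coef(ref)[f]),
                 tolerance = 1e-3)
  }
})

test_that("the cascade respects containment and produces linear RadScores", {
  toy <- make_feature_toy(n = 150, m = 12, seed = 9, effect = 1.5)
  model <- fit_radscore(toy$X, toy$y, seed = 2)
  surv <- model$screening$feature[model$screening$survivor]
  expect_true(all(model$mrmr %in% surv))
  expect_true(all(model$features %in% model$mrmr))
  # linearity: doubling one z-value moves the score by coef * z
  sc <- compute_radscore(model, toy$X)
  expect_identical(sc, model$train_scores)
  if (length(model$features)) {
    f <- model$features[1]
    cf <- model$coefficients[f]
    tab2 <- toy$X
    mu <- model$normalization$mean[f]
    sdv <- model$normalization$sd[f]
    z0 <- (tab2[[f]] - mu) / sdv
    tab2[[f]] <- tab2[[f]] + z0 * sdv # doubles the z-score
    sc2 <- compute_radscore(model, tab2)
    expect_equal(sc2 - sc, unname(cf) * z0, tolerance = 1e-10)
  }
  # all-zero model gives the constant intercept
  null_model <- model
  null_model$features <- character(0)
  null_model$coefficients <- numeric(0)
  null_model$intercept <- 0.37
  expect_identical(compute_radscore(null_model, toy$X),
                   rep(0.37, nrow(toy$X)))
})

test_that("positive-class RadScores exceed negative-class on implanted signal", {
  toy <- make_feature_toy(n = 200, m = 10, seed = 10, effect = 1.2)
  model <- fit_radscore(toy$X, toy$y, seed = 3)
  sc <- compute_radscore(model, toy$X)
  expect_gt(mean(sc[toy$y == 1]), mean(sc[toy$y == 0]))
})

test_that("fitting never touches held-out rows (no leakage)", {
  toy <- make_feature_toy(n = 100, m = 8, seed = 11, effect = 1)
  m1 <- fit_radscore(toy$X[1:60, ], toy$y[1:60], seed = 4)
  m2 <- fit_radscore(toy$X[1:60, ], toy$y[1:60], seed = 4)
  expect_identical(tidy(m1), tidy(m2))
  expect_identical(m1$normalization$mean, m2$normalization$mean)
})

test_that("under the global null the cascade stays near-empty", {
  counts <- vapply(1:20, function(s) {
    toy <- make_feature_toy(n = 80, m = 40, seed = 200 + s, effect = 0)
    m <- fit_radscore(toy$X, toy$y, seed = s)
    length(m$features)
  }, 1.0)
  expect_lte(median(counts), 2)
})

test_that("RadScore models serialize to JSON and back", {
  toy <- make_feature_toy(n = 120, m = 6, seed = 12, effect = 2)
  model <- fit_radscore(toy$X, toy$y, seed = 5)
  path <- tempfile(fileext = ".json")
  radscore_to_json(model, path)
  back <- radscore_from_json(path)
  expect_equal(compute_radscore(back, toy$X), compute_radscore(model, toy$X),
               tolerance = 1e-12)
  unlink(path)
})
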