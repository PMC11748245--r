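#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie handling:
#' `AUC = (mean rank of positives - (n1 + 1) / 2) / n0`. Equals trapezoidal
#' integration of the empirical ROC curve.
#'
#' @param scores numeric predictions (larger = more positive).
#' @param labels binary labels (0/1).
#' @return scalar AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Stratified bootstrap (resampling within each class, preserving class
#' sizes) with `B` replicates; the interval is the percentile interval of
#' the bootstrap AUC distribution.
#'
#' @inheritParams roc_auc
#' @param B number of bootstrap replicates (default 1000).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return a list with `auc`, `lower`, `upper`, `B`.
#' @export
bootstrap_ci <- function(scores, labels, B = 1000L, conf = 0.95, seed = 1L) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  point <- roc_auc(scores, labels)
  aucs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      roc_auc(scores[idx], labels[idx])
    }, 1.0)
  })
  qs <- stats::quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(auc = point, lower = qs[1], upper = qs[2], B = as.integer(B))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two models scored on the same patients, using the
#' placement-value (structural component) covariance estimator; two-sided
#' p from the normal reference. The statistic is antisymmetric in the two
#' score vectors. Identical score vectors give `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b predictions of the two models on the same
#'   samples.
#' @param labels binary labels (at least two per class).
#' @return a list with `auc_a`, `auc_b`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  m <- length(pos)
  n <- length(neg)
  if (m < 2L || n < 2L) abort("DeLong test needs at least 2 samples per class")
  placements <- function(s) {
    x <- s[pos]
    y <- s[neg]
    # midrank placements: V10_i = P(X_i > Y) + 0.5 P(X_i = Y)
    v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n, 1.0)
    v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m, 1.0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' Decision curve analysis
#'
#' Net benefit of acting on predicted probabilities at each threshold
#' probability `pt`: `NB(pt) = TP/n - FP/n * pt / (1 - pt)`, where a
#' patient is treated when the predicted probability exceeds `pt`.
#' Includes the treat-all and treat-none reference policies. Net benefit
#' never exceeds the prevalence.
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels binary labels.
#' @param thresholds threshold-probability grid (default 0.01–0.60 by 0.01).
#' @return An object of class `decision_curve`: a tibble with columns
#'   `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(probs, labels, thresholds = seq(0.01, 0.60, 0.01)) {
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  rows <- lapply(thresholds, function(pt) {
    treat <- probs > pt
    tp <- sum(treat & labels == 1L) / n
    fp <- sum(treat & labels == 0L) / n
    w <- pt / (1 - pt)
    tibble(
      threshold = pt,
      net_benefit = tp - fp * w,
      treat_all = prev - (1 - prev) * w,
      treat_none = 0
    )
  })
  structure(dplyr::bind_rows(rows), class = c("decision_curve", class(tibble())))
}

#' @export
autoplot.decision_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("net_benefit", "treat_all", "treat_none"),
                            names_to = "policy", values_to = "nb")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                   color = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit",
                  color = NULL) +
    ggplot2::theme_minimal()
}

# Youden-optimal threshold (maximizes sensitivity + specificity - 1) on a
# score vector; returns the score cutoff.
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  cuts <- sort(unique(scores))
  if (length(cuts) > 1L) {
    cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
  }
  j <- vapply(cuts, function(ct) {
    sens <- mean(scores[labels == 1L] > ct)
    spec <- mean(scores[labels == 0L] <= ct)
    sens + spec - 1
  }, 1.0)
  cuts[which.max(j)]
}

classification_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  list(
    accuracy = mean(pred == labels),
    sensitivity = if (any(labels == 1L)) mean(pred[labels == 1L] == 1L) else NA_real_,
    specificity = if (any(labels == 0L)) mean(pred[labels == 0L] == 0L) else NA_real_
  )
}
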