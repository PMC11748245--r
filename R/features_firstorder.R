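#' First-order intensity statistics (19 features)
#'
#' IBSI-style first-order features of the in-mask intensity distribution.
#' `Entropy` and `Uniformity` are computed on the discretized histogram
#' (entropy in bits); moments use population (1/N) denominators. For a
#' constant region the skewness and kurtosis are defined as 0 (no-NaN
#' convention, documented), variance and entropy are 0 and uniformity is 1.
#'
#' @param x numeric vector of in-mask intensities.
#' @param cfg a [discretization_config()] for the histogram features.
#' @param voxel_volume_mm3 voxel volume used by `TotalEnergy`.
#' @return named numeric vector of 19 features (prefix `firstorder_`).
#' @export
first_order_features <- function(x, cfg = discretization_config(),
                                 voxel_volume_mm3 = 1) {
  if (length(x) == 0L) abort("empty region")
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mu)^4) / v^2 else 0
  lev <- discretize(x, cfg)$levels
  p <- tabulate(lev) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  c(
    firstorder_Mean = mu,
    firstorder_Median = q[3],
    firstorder_Minimum = min(x),
    firstorder_Maximum = max(x),
    firstorder_Range = max(x) - min(x),
    firstorder_Percentile10 = q[1],
    firstorder_Percentile90 = q[5],
    firstorder_InterquartileRange = q[4] - q[2],
    firstorder_Variance = v,
    firstorder_StandardDeviation = s,
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = voxel_volume_mm3 * sum(x^2),
    firstorder_Entropy = -sum(p * log2(p)),
    firstorder_Uniformity = sum(p^2)
  )
}
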