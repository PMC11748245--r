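#' Gray-level discretization configuration
#'
#' Radiomic texture features operate on discretized gray levels. Two IBSI
#' schemes are supported: fixed bin width (`level = floor((x - min) / w) + 1`,
#' default width 25 HU, the common CT radiomics choice) and fixed bin count
#' (equal-width bins over the observed `[min, max]`). An optional
#' resegmentation range clips intensities before discretization.
#'
#' @param mode `"fixed_bin_width"` or `"fixed_bin_count"`.
#' @param bin_width bin width in HU (fixed-bin-width mode).
#' @param bin_count number of bins (fixed-bin-count mode).
#' @param resegmentation_range optional length-2 HU interval.
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(mode = c("fixed_bin_width", "fixed_bin_count"),
                                  bin_width = 25, bin_count = 32L,
                                  resegmentation_range = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_bin_width" && (!is.finite(bin_width) || bin_width <= 0)) {
    abort("`bin_width` must be positive")
  }
  if (mode == "fixed_bin_count" && (!is.finite(bin_count) || bin_count < 1)) {
    abort("`bin_count` must be a positive integer")
  }
  if (!is.null(resegmentation_range) &&
      (length(resegmentation_range) != 2L || diff(resegmentation_range) <= 0)) {
    abort("`resegmentation_range` must be an increasing HU interval")
  }
  structure(
    list(mode = mode, bin_width = bin_width, bin_count = as.integer(bin_count),
         resegmentation_range = resegmentation_range),
    class = "discretization_config"
  )
}

#' Discretize intensities to integer gray levels
#'
#' @param x numeric vector of in-mask intensities.
#' @param cfg a [discretization_config()].
#' @return a list with `levels` (integers starting at 1) and `n_levels`.
#' @examples
#' discretize(c(0, 25, 50), discretization_config(bin_width = 25))
#' @export
discretize <- function(x, cfg = discretization_config()) {
  if (length(x) == 0L) abort("cannot discretize an empty region")
  if (!is.null(cfg$resegmentation_range)) {
    x <- pmin(pmax(x, cfg$resegmentation_range[1]), cfg$resegmentation_range[2])
  }
  lo <- min(x)
  hi <- max(x)
  if (cfg$mode == "fixed_bin_width") {
    lev <- as.integer(floor((x - lo) / cfg$bin_width)) + 1L
  } else {
    if (hi == lo) {
      lev <- rep(1L, length(x))
    } else {
      lev <- as.integer(ceiling((x - lo) / (hi - lo) * cfg$bin_count))
      lev[lev < 1L] <- 1L
      lev[lev > cfg$bin_count] <- cfg$bin_count
    }
  }
  list(levels = lev, n_levels = max(lev))
}

# Discretize an image restricted to a mask: integer array, 0 outside mask.
discretize_volume <- function(image, mask, cfg) {
  arr <- as_array3d(image)
  mask <- check_mask(mask, arr)
  d <- discretize(arr[mask], cfg)
  lev <- array(0L, dim(arr))
  lev[mask] <- d$levels
  list(levels = lev, n_levels = d$n_levels)
}
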