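#' Structural similarity index (SSIM)
#'
#' Mean SSIM between two images (2D or 3D) using the conventional Gaussian
#' window (sd 1.5, 11 taps per axis, renormalized at edges) and stabilizing
#' constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with `K = (0.01, 0.03)` and
#' `L` the joint dynamic range. Symmetric in its arguments; identical
#' images give exactly 1. When both images are constant the convention
#' `L = 1` applies (identical constants still give 1).
#'
#' @param a,b numeric arrays of identical shape.
#' @param window_sigma Gaussian window sd in voxels.
#' @param window_size window width (odd).
#' @param K the two stabilizing fractions.
#' @param data_range dynamic range `L`; joint range of both images when
#'   `NULL`.
#' @return scalar SSIM in `[-1, 1]`.
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' compute_ssim(x, x)
#' @export
compute_ssim <- function(a, b, window_sigma = 1.5, window_size = 11L,
                         K = c(0.01, 0.03), data_range = NULL) {
  a <- as_array3d(a)
  b <- as_array3d(b)
  if (!identical(dim(a), dim(b))) abort("images must have the same shape")
  if (is.null(data_range)) {
    data_range <- max(a, b) - min(a, b)
    if (data_range == 0) data_range <- 1
  }
  r <- (window_size - 1L) %/% 2L
  k <- exp(-(seq(-r, r))^2 / (2 * window_sigma^2))
  smooth <- function(x) {
    for (axis in 1:3) {
      if (dim(x)[axis] > 1L) x <- filter_axis(x, k, axis, normalize = TRUE)
    }
    x
  }
  mu_a <- smooth(a)
  mu_b <- smooth(b)
  var_a <- smooth(a * a) - mu_a^2
  var_b <- smooth(b * b) - mu_b^2
  cov_ab <- smooth(a * b) - mu_a * mu_b
  c1 <- (K[1] * data_range)^2
  c2 <- (K[2] * data_range)^2
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(ssim_map)
}

#' Adjacent-pixel correlation audit
#'
#' Pearson correlation between `n_pairs` randomly sampled pairs of adjacent
#' pixels in the requested direction(s), the standard statistical-attack
#' audit for image ciphers: natural CT slices correlate strongly, a secure
#' ciphertext rendered as pixels should correlate near zero. A zero-variance
#' sample is flagged as undefined rather than propagating `NaN`.
#'
#' @param image a numeric matrix (use [ciphertext_image()] to render an
#'   encrypted ROI as pixels).
#' @param direction subset of `"horizontal"`, `"vertical"`, `"diagonal"`.
#' @param n_pairs number of sampled pairs.
#' @param seed integer seed for the pair sample.
#' @return a tibble with columns `direction`, `r`, `n_pairs`, `defined`.
#' @export
pixel_correlation <- function(image,
                              direction = c("horizontal", "vertical", "diagonal"),
                              n_pairs = 5000L, seed = 1L) {
  direction <- match.arg(direction, several.ok = TRUE)
  if (inherits(image, "image_volume")) image <- image$data
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 1L) {
    image <- image[, , 1]
  }
  if (!is.matrix(image)) abort("`image` must be a 2D matrix (or single-slice volume)")
  offs <- list(horizontal = c(0L, 1L), vertical = c(1L, 0L), diagonal = c(1L, 1L))
  rows <- lapply(direction, function(d) {
    o <- offs[[d]]
    nr <- nrow(image) - o[1]
    nc <- ncol(image) - o[2]
    if (nr < 1L || nc < 1L) abort("image too small to sample adjacent pairs")
    with_seed(seed, {
      i <- sample.int(nr, n_pairs, replace = TRUE)
      j <- sample.int(nc, n_pairs, replace = TRUE)
    })
    x <- image[cbind(i, j)]
    y <- image[cbind(i + o[1], j + o[2])]
    if (sd(x) == 0 || sd(y) == 0) {
      tibble(direction = d, r = NA_real_, n_pairs = as.integer(n_pairs),
             defined = FALSE)
    } else {
      tibble(direction = d, r = cor(x, y), n_pairs = as.integer(n_pairs),
             defined = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Render ciphertext bytes as a pixel matrix
#'
#' Reshapes the ciphertext byte stream of an encrypted ROI into a
#' near-square matrix of byte values (0–255), the representation used for
#' the pixel-correlation security audit.
#'
#' @param enc an `encrypted_roi`.
#' @return an integer matrix.
#' @export
ciphertext_image <- function(enc) {
  stopifnot(inherits(enc, "encrypted_roi"))
  v <- as.integer(enc$ciphertext)
  nr <- floor(sqrt(length(v)))
  nc <- length(v) %/% nr
  matrix(v[seq_len(nr * nc)], nr, nc)
}

#' Encryption fidelity and security report
#'
#' Runs the full audit for one ROI: encrypt, decrypt, verify the lossless
#' round trip via SSIM, and compare directional adjacent-pixel correlations
#' of the plaintext slice against the ciphertext rendering.
#'
#' @param x an [image_volume()] or array.
#' @param key 32-byte key.
#' @param n_pairs,seed passed to [pixel_correlation()].
#' @return An object of class `security_report`: list with `ssim_roundtrip`,
#'   `bit_identical` and a `correlations` tibble (columns `image`,
#'   `direction`, `r`, `defined`).
#' @export
security_report <- function(x, key, n_pairs = 5000L, seed = 1L) {
  key <- rad_key(key)
  arr <- as_array3d(x)
  enc <- encrypt_roi(x, key)
  dec <- decrypt_roi(enc, key)
  mid <- ceiling(dim(arr)[3] / 2)
  plain <- pixel_correlation(arr[, , mid], n_pairs = n_pairs, seed = seed) %>%
    mutate(image = "plaintext")
  cipher <- pixel_correlation(ciphertext_image(enc), n_pairs = n_pairs,
                              seed = seed) %>%
    mutate(image = "ciphertext")
  structure(
    list(
      ssim_roundtrip = compute_ssim(arr, dec$data),
      bit_identical = identical(as.numeric(arr), as.numeric(dec$data)),
      correlations = dplyr::bind_rows(plain, cipher) %>%
        select("image", "direction", "r", "n_pairs", "defined")
    ),
    class = "security_report"
  )
}

#' @export
print.security_report <- function(x, ...) {
  cat(sprintf("<security_report> round-trip SSIM = %g (bit-identical: %s)\n",
              x$ssim_roundtrip, x$bit_identical))
  print(x$correlations)
  invisible(x)
}
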