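# One-level stationary (undecimated) separable wavelet decomposition.
#
# Coiflet-1 analysis filters (orthonormal; low-pass coefficients sum to
# sqrt(2)). Hard-coded because no wavelet package ships with the
# environment; values match the standard published coif1 filter bank.
.coif1_lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
               0.852572020212255, 0.337897662457809, -0.072732619512854)

# quadrature mirror high-pass: g[k] = (-1)^k h[L-1-k]
.coif1_hi <- rev(.coif1_lo) * c(1, -1, 1, -1, 1, -1)

# circular (periodic) convolution of a 3D array with a 1D kernel along one
# axis, kernel center aligned on each voxel (zero phase up to the integer
# center tap).
circ_filter_axis <- function(arr, k, axis) {
  d <- dim(arr)
  n <- d[axis]
  kk <- numeric(n)
  ctr <- floor(length(k) / 2) # center tap index (1-based ctr+1)
  for (t in seq_along(k)) {
    pos <- ((t - 1 - ctr) %% n) + 1
    kk[pos] <- kk[pos] + k[t]
  }
  H <- fft(kk)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  res <- Re(stats::mvfft(stats::mvfft(m) * H, inverse = TRUE)) / n
  aperm(array(res, d[perm]), order(perm))
}

#' One-level wavelet sub-band images
#'
#' Undecimated (stationary) single-level separable wavelet decomposition
#' with the coif1 filter bank and periodic boundary handling. Sub-bands keep
#' the input grid, so segmentation masks apply unchanged. A 3D input yields
#' the 8 low/high-pass combinations `LLL` … `HHH` (letter `i` = filter along
#' axis `i`); single-slice inputs yield the 4 planar combinations `LL` …
#' `HH`. With these orthonormal filters the sub-band energies sum to
#' `2^d` times the input energy (`d` = number of filtered axes).
#'
#' @param x an [image_volume()], matrix or array.
#' @param wavelet currently `"coif1"`.
#' @return named list of arrays, one per sub-band.
#' @export
wavelet_subbands <- function(x, wavelet = "coif1") {
  if (!identical(wavelet, "coif1")) abort("only the coif1 wavelet is built in")
  arr <- as_array3d(x)
  d <- dim(arr)
  planar <- d[3] == 1L
  axes <- if (planar) 1:2 else 1:3
  combos <- expand.grid(rep(list(c("L", "H")), length(axes)),
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  names(out) <- apply(combos, 1, paste, collapse = "")
  for (r in seq_len(nrow(combos))) {
    sub <- arr
    for (a in seq_along(axes)) {
      k <- if (combos[r, a] == "L") .coif1_lo else .coif1_hi
      if (d[axes[a]] > 1L) sub <- circ_filter_axis(sub, k, axes[a])
    }
    out[[r]] <- sub
  }
  out
}
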