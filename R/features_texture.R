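# Texture-matrix feature families (GLCM / GLRLM / GLSZM / NGTDM / GLDM).
#
# The counting kernels live in src/texture.cpp; this file normalizes the
# matrices and evaluates the IBSI-style feature formulas. Entropies are in
# bits and computed over strictly positive probabilities (no epsilon
# padding). Offset/direction-resolved families (GLCM, GLRLM) evaluate the
# features per offset and average; offsets that produce no voxel pairs
# (possible for planar masks probed out of plane) are excluded from the
# average.

# 13 unique 3D direction vectors at Chebyshev distance 1; 4 in-plane ones
# for planar (single-slice) inputs.
texture_offsets <- function(planar = FALSE) {
  o <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  if (planar) o[1:4, , drop = FALSE] else o
}

ent2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Symmetric co-occurrence matrices at all unit offsets (13 directions in
#' 3D, 4 in-plane for single-slice inputs), normalized to probabilities;
#' the 24 features are evaluated per offset and averaged.
#'
#' @param levels integer array of gray levels (1..`n_levels` in the mask, 0
#'   outside), as produced by the discretization step.
#' @param n_levels number of gray levels.
#' @param offsets optional integer matrix of direction vectors (rows).
#' @return named numeric vector of 24 features (prefix `glcm_`).
#' @export
glcm_features <- function(levels, n_levels, offsets = NULL) {
  levels <- as_levels3d(levels)
  if (sum(levels > 0) < 2L) abort("GLCM requires at least 2 in-mask voxels")
  if (is.null(offsets)) texture_guard(levels)
  offs <- if (is.null(offsets)) texture_offsets(dim(levels)[3] == 1L) else offsets
  counts <- .glcm_counts(levels, dim(levels), n_levels, offs)
  per <- lapply(seq_len(dim(counts)[3]), function(o) {
    glcm_features_one(matrix(counts[, , o], n_levels, n_levels),
                      n_levels = n_levels)
  })
  keep <- !vapply(per, is.null, TRUE)
  if (!any(keep)) abort("no voxel pairs found for any GLCM offset")
  rowMeans(do.call(cbind, per[keep]))
}

# per-size cache of GLCM index matrices (row/col indices and their
# differences/sums), reused across offsets and regions
.glcm_idx_cache <- new.env(parent = emptyenv())

glcm_idx <- function(Ng) {
  key <- as.character(Ng)
  hit <- .glcm_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- matrix(rep(seq_len(Ng), Ng), Ng, Ng)
  j <- t(i)
  out <- list(i = i, j = j, d2 = (i - j)^2, absd = abs(i - j), s = i + j,
              ij = i * j, offdiag = i != j)
  .glcm_idx_cache[[key]] <- out
  out
}

glcm_features_one <- function(M, n_levels) {
  tot <- sum(M)
  if (tot == 0) return(NULL)
  P <- M / tot
  Ng <- n_levels
  ix <- glcm_idx(Ng)
  i <- ix$i
  j <- ix$j
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(Ng) * px)
  muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  # diagonal / cross-diagonal marginals (grouped sums over i+j and |i-j|)
  psum <- as.numeric(rowsum(as.numeric(P), as.integer(ix$s)))
  pdiff <- as.numeric(rowsum(as.numeric(P), as.integer(ix$absd)))
  ksum <- 2:(2 * Ng)
  kdiff <- 0:(Ng - 1)
  da <- sum(kdiff * pdiff)
  hxy <- ent2(P)
  hx <- ent2(px)
  hy <- ent2(py)
  pp <- px[i] * py[j]
  pos <- P > 0 & pp > 0
  hxy1 <- -sum(P[pos] * log2(pp[pos]))
  hxy2 <- ent2(pp)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sx > 1e-12 && sy > 1e-12) {
    (sum(ix$ij * P) - mux * muy) / (sx * sy)
  } else {
    1
  }
  # MCC: second-largest eigenvalue of Q(a,b) = sum_k p(a,k)p(b,k)/(px(a)py(k)).
  # Q is similar to the symmetric PSD matrix M M' with
  # M = diag(px)^-1/2 P diag(py)^-1/2, so the well-conditioned symmetric
  # eigendecomposition is used.
  mcc <- if (Ng > 1) {
    sx0 <- sqrt(ifelse(px > 0, px, 1))
    sy0 <- sqrt(ifelse(py > 0, py, 1))
    M2 <- P / sx0
    M2 <- t(t(M2) / sy0)
    ev <- sort(eigen(tcrossprod(M2), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    sqrt(pmax(0, ev[2]))
  } else {
    1
  }
  clus <- ix$s - mux - muy
  c(
    glcm_Autocorrelation = sum(ix$ij * P),
    glcm_JointAverage = mux,
    glcm_ClusterProminence = sum(clus^4 * P),
    glcm_ClusterShade = sum(clus^3 * P),
    glcm_ClusterTendency = sum(clus^2 * P),
    glcm_Contrast = sum(ix$d2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = ent2(pdiff),
    glcm_DifferenceVariance = sum((kdiff - da)^2 * pdiff),
    glcm_Id = sum(P / (1 + ix$absd)),
    glcm_Idm = sum(P / (1 + ix$d2)),
    glcm_Idmn = sum(P / (1 + ix$d2 / Ng^2)),
    glcm_Idn = sum(P / (1 + ix$absd / Ng)),
    glcm_Imc1 = imc1,
    glcm_Imc2 = imc2,
    glcm_InverseVariance = sum(P[ix$offdiag] / ix$d2[ix$offdiag]),
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = hxy,
    glcm_MCC = mcc,
    glcm_MaximumProbability = max(P),
    glcm_SumAverage = sum(ksum * psum),
    glcm_SumEntropy = ent2(psum),
    glcm_SumSquares = sum((i - mux)^2 * P)
  )
}

#' Gray-level run-length (GLRLM) features
#'
#' Run-length matrices per direction (13 in 3D, 4 in-plane), features
#' evaluated per direction and averaged.
#'
#' @inheritParams glcm_features
#' @param directions optional direction matrix.
#' @return named numeric vector of 16 features (prefix `glrlm_`).
#' @export
glrlm_features <- function(levels, n_levels, directions = NULL) {
  levels <- as_levels3d(levels)
  if (is.null(directions)) texture_guard(levels)
  dirs <- if (is.null(directions)) texture_offsets(dim(levels)[3] == 1L) else directions
  counts <- .glrlm_counts(levels, dim(levels), n_levels, dirs)
  np <- sum(levels > 0)
  per <- lapply(seq_len(dim(counts)[3]), function(o) {
    glrlm_features_one(matrix(counts[, , o], dim(counts)[1], dim(counts)[2]),
                       np = np)
  })
  keep <- !vapply(per, is.null, TRUE)
  if (!any(keep)) abort("no runs found for any direction")
  rowMeans(do.call(cbind, per[keep]))
}

glrlm_features_one <- function(R, np) {
  nr <- sum(R)
  if (nr == 0) return(NULL)
  i <- row(R)
  l <- col(R)
  p <- R / nr
  mug <- sum(i * p)
  mul <- sum(l * p)
  c(
    glrlm_ShortRunEmphasis = sum(R / l^2) / nr,
    glrlm_LongRunEmphasis = sum(R * l^2) / nr,
    glrlm_GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    glrlm_GrayLevelNonUniformityNormalized = sum(rowSums(R)^2) / nr^2,
    glrlm_RunLengthNonUniformity = sum(colSums(R)^2) / nr,
    glrlm_RunLengthNonUniformityNormalized = sum(colSums(R)^2) / nr^2,
    glrlm_RunPercentage = nr / np,
    glrlm_GrayLevelVariance = sum((i - mug)^2 * p),
    glrlm_RunVariance = sum((l - mul)^2 * p),
    glrlm_RunEntropy = ent2(p),
    glrlm_LowGrayLevelRunEmphasis = sum(R / i^2) / nr,
    glrlm_HighGrayLevelRunEmphasis = sum(R * i^2) / nr,
    glrlm_ShortRunLowGrayLevelEmphasis = sum(R / (i^2 * l^2)) / nr,
    glrlm_ShortRunHighGrayLevelEmphasis = sum(R * i^2 / l^2) / nr,
    glrlm_LongRunLowGrayLevelEmphasis = sum(R * l^2 / i^2) / nr,
    glrlm_LongRunHighGrayLevelEmphasis = sum(R * i^2 * l^2) / nr
  )
}

#' Gray-level size-zone (GLSZM) features
#'
#' Zones are connected components of equal gray level (26-connectivity in
#' 3D, 8-connectivity in-plane). Rotation-invariant, so no direction
#' averaging.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features (prefix `glszm_`).
#' @export
glszm_features <- function(levels, n_levels) {
  levels <- as_levels3d(levels)
  zones <- .glszm_zones(levels, dim(levels))
  np <- sum(levels > 0)
  if (nrow(zones) == 0L) abort("no zones found (empty mask)")
  i <- zones[, 1]
  s <- zones[, 2]
  nz <- nrow(zones)
  p <- rep(1 / nz, nz)
  mug <- sum(i * p)
  mus <- sum(s * p)
  glev <- tapply(rep(1, nz), factor(i, levels = seq_len(n_levels)), sum,
                 default = 0)
  gsize <- tapply(rep(1, nz), factor(s), sum)
  pj <- as.numeric(table(interaction(i, s, drop = TRUE))) / nz
  c(
    glszm_SmallAreaEmphasis = sum(1 / s^2) / nz,
    glszm_LargeAreaEmphasis = sum(s^2) / nz,
    glszm_GrayLevelNonUniformity = sum(glev^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(glev^2) / nz^2,
    glszm_SizeZoneNonUniformity = sum(gsize^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(gsize^2) / nz^2,
    glszm_ZonePercentage = nz / np,
    glszm_GrayLevelVariance = sum((i - mug)^2 * p),
    glszm_ZoneVariance = sum((s - mus)^2 * p),
    glszm_ZoneEntropy = ent2(pj),
    glszm_LowGrayLevelZoneEmphasis = sum(1 / i^2) / nz,
    glszm_HighGrayLevelZoneEmphasis = sum(i^2) / nz,
    glszm_SmallAreaLowGrayLevelEmphasis = sum(1 / (i^2 * s^2)) / nz,
    glszm_SmallAreaHighGrayLevelEmphasis = sum(i^2 / s^2) / nz,
    glszm_LargeAreaLowGrayLevelEmphasis = sum(s^2 / i^2) / nz,
    glszm_LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2) / nz
  )
}

#' Neighborhood gray-tone difference (NGTDM) features
#'
#' Based on the absolute difference between each voxel's level and the mean
#' level of its 26-neighborhood (8 in-plane). Degenerate cases follow the
#' stated conventions: a constant region has coarseness at the defined
#' maximum (1e6) and zero contrast/busyness/complexity/strength.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features (prefix `ngtdm_`).
#' @export
ngtdm_features <- function(levels, n_levels) {
  levels <- as_levels3d(levels)
  cs <- .ngtdm_counts(levels, dim(levels), n_levels)
  ngtdm_features_from_counts(cs[, 1], cs[, 2])
}

ngtdm_features_from_counts <- function(n_i, s_i) {
  N <- sum(n_i)
  if (N == 0) abort("no valid NGTDM voxels")
  p <- n_i / N
  lev <- seq_along(n_i)
  act <- which(p > 0)
  ngp <- length(act)
  coarse_den <- sum(p * s_i)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  contrast <- if (ngp > 1) {
    g <- as.matrix(expand.grid(act, act))
    sum(p[g[, 1]] * p[g[, 2]] * (lev[g[, 1]] - lev[g[, 2]])^2) /
      (ngp * (ngp - 1)) * sum(s_i) / N
  } else {
    0
  }
  g <- as.matrix(expand.grid(act, act))
  ii <- g[, 1]
  jj <- g[, 2]
  busy_den <- sum(abs(lev[ii] * p[ii] - lev[jj] * p[jj]))
  complexity <- sum(abs(lev[ii] - lev[jj]) *
                      (p[ii] * s_i[ii] + p[jj] * s_i[jj]) /
                      (p[ii] + p[jj])) / N
  strength_num <- sum((p[ii] + p[jj]) * (lev[ii] - lev[jj])^2)
  busyness <- if (busy_den > 0) sum(p * s_i) / busy_den else 0
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  c(
    ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength
  )
}

#' Gray-level dependence (GLDM) features
#'
#' The dependence of a voxel is the number of 26-neighbors (8 in-plane)
#' whose level differs from the center by at most `alpha` (default 0); the
#' matrix counts voxels by (level, dependence + 1).
#'
#' @inheritParams glcm_features
#' @param alpha dependence tolerance in gray levels.
#' @return named numeric vector of 14 features (prefix `gldm_`).
#' @export
gldm_features <- function(levels, n_levels, alpha = 0L) {
  levels <- as_levels3d(levels)
  D <- .gldm_counts(levels, dim(levels), n_levels, as.integer(alpha))
  gldm_features_from_matrix(D)
}

gldm_features_from_matrix <- function(D) {
  nz <- sum(D)
  if (nz == 0) abort("empty GLDM")
  i <- row(D)
  j <- col(D) # dependence size = k + 1
  p <- D / nz
  mug <- sum(i * p)
  mud <- sum(j * p)
  c(
    gldm_SmallDependenceEmphasis = sum(D / j^2) / nz,
    gldm_LargeDependenceEmphasis = sum(D * j^2) / nz,
    gldm_GrayLevelNonUniformity = sum(rowSums(D)^2) / nz,
    gldm_DependenceNonUniformity = sum(colSums(D)^2) / nz,
    gldm_DependenceNonUniformityNormalized = sum(colSums(D)^2) / nz^2,
    gldm_GrayLevelVariance = sum((i - mug)^2 * p),
    gldm_DependenceVariance = sum((j - mud)^2 * p),
    gldm_DependenceEntropy = ent2(p),
    gldm_LowGrayLevelEmphasis = sum(D / i^2) / nz,
    gldm_HighGrayLevelEmphasis = sum(D * i^2) / nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(D / (i^2 * j^2)) / nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(D * i^2 / j^2) / nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(D * j^2 / i^2) / nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(D * i^2 * j^2) / nz
  )
}

as_levels3d <- function(levels) {
  if (is.matrix(levels)) levels <- array(levels, c(dim(levels), 1L))
  if (!is.array(levels) || length(dim(levels)) != 3L) {
    abort("`levels` must be a 2D/3D integer array")
  }
  storage.mode(levels) <- "integer"
  levels
}

texture_guard <- function(levels) {
  if (!any(levels > 0)) abort("empty mask")
  invisible(TRUE)
}
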