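# Brute-force oracles, written independently of the package implementation:
# plain R loops over voxels / matrix cells, no shared counting or formula
# code. Used to pin every texture feature and the ring geometry.

fixed_key <- function() as.raw(1:32)

rand_level_array <- function(dims, n_levels, p_mask = 0.7) {
  lev <- array(0L, dims)
  m <- array(runif(prod(dims)) < p_mask, dims)
  lev[m] <- sample.int(n_levels, sum(m), replace = TRUE)
  lev
}

# all 26-neighborhood (or in-plane 8) neighbor coordinates
all_neighbors <- function(co, dims) {
  out <- list()
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    p <- co + c(di, dj, dk)
    if (all(p >= 1) && all(p <= dims)) out[[length(out) + 1]] <- p
  }
  out
}

oracle_glcm_matrix <- function(lev, offset) {
  dims <- dim(lev)
  n_levels <- max(lev)
  M <- matrix(0, n_levels, n_levels)
  vox <- which(lev > 0, arr.ind = TRUE)
  for (a in seq_len(nrow(vox))) {
    for (b in seq_len(nrow(vox))) {
      if (a == b) next
      d <- vox[b, ] - vox[a, ]
      if (all(d == offset) || all(d == -offset)) {
        M[lev[vox[a, , drop = FALSE]], lev[vox[b, , drop = FALSE]]] <-
          M[lev[vox[a, , drop = FALSE]], lev[vox[b, , drop = FALSE]]] + 1
      }
    }
  }
  M
}

# vectorized variant of the pair enumeration (coordinate lookup + tabulation)
# for the 50-mask sweeps; the O(n^2) all-pairs version above stays as the
# slow cross-check on a few masks
oracle_glcm_matrix_fast <- function(lev, offset) {
  dims <- dim(lev)
  n_levels <- max(lev)
  vox <- which(lev > 0, arr.ind = TRUE)
  tgt <- sweep(vox, 2, offset, `+`)
  ok <- tgt[, 1] >= 1 & tgt[, 1] <= dims[1] &
    tgt[, 2] >= 1 & tgt[, 2] <= dims[2] &
    tgt[, 3] >= 1 & tgt[, 3] <= dims[3]
  a <- lev[vox[ok, , drop = FALSE]]
  b <- lev[tgt[ok, , drop = FALSE]]
  keep <- b > 0
  M <- matrix(0, n_levels, n_levels)
  for (t in which(keep)) M[a[t], b[t]] <- M[a[t], b[t]] + 1
  M + t(M)
}

oracle_glcm_features <- function(M) {
  Ng <- nrow(M)
  P <- M / sum(M)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:Ng) { sx <- sx + (i - mux)^2 * px[i]; sy <- sy + (i - muy)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  psum <- numeric(2 * Ng); pdiff <- numeric(Ng)
  f <- c(Autocorrelation = 0, JointAverage = mux, ClusterProminence = 0,
         ClusterShade = 0, ClusterTendency = 0, Contrast = 0,
         JointEnergy = 0, JointEntropy = 0, Id = 0, Idm = 0, Idmn = 0,
         Idn = 0, InverseVariance = 0, MaximumProbability = max(P),
         SumSquares = 0)
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * p
    f["ClusterProminence"] <- f["ClusterProminence"] + (i + j - mux - muy)^4 * p
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - mux - muy)^3 * p
    f["ClusterTendency"] <- f["ClusterTendency"] + (i + j - mux - muy)^2 * p
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * p
    f["JointEnergy"] <- f["JointEnergy"] + p^2
    if (p > 0) f["JointEntropy"] <- f["JointEntropy"] - p * log2(p)
    f["Id"] <- f["Id"] + p / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + p / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + p / (1 + ((i - j) / Ng)^2)
    f["Idn"] <- f["Idn"] + p / (1 + abs(i - j) / Ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + p / (i - j)^2
    f["SumSquares"] <- f["SumSquares"] + (i - mux)^2 * p
  }
  ent <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  da <- sum((0:(Ng - 1)) * pdiff)
  corr <- if (sx > 1e-12 && sy > 1e-12) {
    (f[["Autocorrelation"]] - mux * muy) / (sx * sy)
  } else 1
  hx <- ent(px); hy <- ent(py); hxy <- f[["JointEntropy"]]
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  # symmetrized form of the MCC matrix (similarity transform of Q)
  Mm <- matrix(0, Ng, Ng)
  for (a in 1:Ng) for (k in 1:Ng) {
    if (px[a] > 0 && py[k] > 0) Mm[a, k] <- P[a, k] / sqrt(px[a] * py[k])
  }
  Gm <- matrix(0, Ng, Ng)
  for (a in 1:Ng) for (b in 1:Ng) {
    s <- 0
    for (k in 1:Ng) s <- s + Mm[a, k] * Mm[b, k]
    Gm[a, b] <- s
  }
  mcc <- if (Ng > 1) {
    ev <- sort(eigen(Gm, symmetric = TRUE)$values, decreasing = TRUE)
    sqrt(max(0, ev[2]))
  } else 1
  c(
    glcm_Autocorrelation = f[["Autocorrelation"]],
    glcm_JointAverage = mux,
    glcm_ClusterProminence = f[["ClusterProminence"]],
    glcm_ClusterShade = f[["ClusterShade"]],
    glcm_ClusterTendency = f[["ClusterTendency"]],
    glcm_Contrast = f[["Contrast"]],
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = ent(pdiff),
    glcm_DifferenceVariance = sum(((0:(Ng - 1)) - da)^2 * pdiff),
    glcm_Id = f[["Id"]],
    glcm_Idm = f[["Idm"]],
    glcm_Idmn = f[["Idmn"]],
    glcm_Idn = f[["Idn"]],
    glcm_Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    glcm_Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    glcm_InverseVariance = f[["InverseVariance"]],
    glcm_JointEnergy = f[["JointEnergy"]],
    glcm_JointEntropy = hxy,
    glcm_MCC = mcc,
    glcm_MaximumProbability = f[["MaximumProbability"]],
    glcm_SumAverage = sum((1:(2 * Ng)) * psum),
    glcm_SumEntropy = ent(psum),
    glcm_SumSquares = f[["SumSquares"]]
  )
}

oracle_glrlm_matrix <- function(lev, dir, maxlen) {
  dims <- dim(lev)
  n_levels <- max(lev)
  R <- matrix(0, n_levels, maxlen)
  vox <- which(array(TRUE, dims), arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    co <- vox[v, ]
    g <- lev[co[1], co[2], co[3]]
    if (g == 0) next
    prev <- co - dir
    if (all(prev >= 1) && all(prev <= dims) &&
        lev[prev[1], prev[2], prev[3]] == g) next
    len <- 1
    nxt <- co + dir
    while (all(nxt >= 1) && all(nxt <= dims) &&
           lev[nxt[1], nxt[2], nxt[3]] == g) {
      len <- len + 1
      nxt <- nxt + dir
    }
    R[g, len] <- R[g, len] + 1
  }
  R
}

oracle_glrlm_features <- function(R, np) {
  nr <- sum(R)
  Ng <- nrow(R); Nl <- ncol(R)
  out <- c(ShortRunEmphasis = 0, LongRunEmphasis = 0,
           GrayLevelNonUniformity = 0, GrayLevelNonUniformityNormalized = 0,
           RunLengthNonUniformity = 0, RunLengthNonUniformityNormalized = 0,
           RunPercentage = nr / np, GrayLevelVariance = 0, RunVariance = 0,
           RunEntropy = 0, LowGrayLevelRunEmphasis = 0,
           HighGrayLevelRunEmphasis = 0, ShortRunLowGrayLevelEmphasis = 0,
           ShortRunHighGrayLevelEmphasis = 0, LongRunLowGrayLevelEmphasis = 0,
           LongRunHighGrayLevelEmphasis = 0)
  mug <- 0; mul <- 0
  for (i in 1:Ng) for (l in 1:Nl) {
    p <- R[i, l] / nr
    mug <- mug + i * p; mul <- mul + l * p
  }
  for (i in 1:Ng) {
    out["GrayLevelNonUniformity"] <- out["GrayLevelNonUniformity"] + sum(R[i, ])^2
  }
  for (l in 1:Nl) {
    out["RunLengthNonUniformity"] <- out["RunLengthNonUniformity"] + sum(R[, l])^2
  }
  for (i in 1:Ng) for (l in 1:Nl) {
    r <- R[i, l]
    p <- r / nr
    out["ShortRunEmphasis"] <- out["ShortRunEmphasis"] + r / l^2
    out["LongRunEmphasis"] <- out["LongRunEmphasis"] + r * l^2
    out["GrayLevelVariance"] <- out["GrayLevelVariance"] + (i - mug)^2 * p
    out["RunVariance"] <- out["RunVariance"] + (l - mul)^2 * p
    if (p > 0) out["RunEntropy"] <- out["RunEntropy"] - p * log2(p)
    out["LowGrayLevelRunEmphasis"] <- out["LowGrayLevelRunEmphasis"] + r / i^2
    out["HighGrayLevelRunEmphasis"] <- out["HighGrayLevelRunEmphasis"] + r * i^2
    out["ShortRunLowGrayLevelEmphasis"] <- out["ShortRunLowGrayLevelEmphasis"] + r / (i^2 * l^2)
    out["ShortRunHighGrayLevelEmphasis"] <- out["ShortRunHighGrayLevelEmphasis"] + r * i^2 / l^2
    out["LongRunLowGrayLevelEmphasis"] <- out["LongRunLowGrayLevelEmphasis"] + r * l^2 / i^2
    out["LongRunHighGrayLevelEmphasis"] <- out["LongRunHighGrayLevelEmphasis"] + r * i^2 * l^2
  }
  for (nm in c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
               "RunLengthNonUniformity", "LowGrayLevelRunEmphasis",
               "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
               "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
               "LongRunHighGrayLevelEmphasis")) {
    out[nm] <- out[nm] / nr
  }
  out["GrayLevelNonUniformityNormalized"] <- out[["GrayLevelNonUniformity"]] / nr
  out["RunLengthNonUniformityNormalized"] <- out[["RunLengthNonUniformity"]] / nr
  names(out) <- paste0("glrlm_", names(out))
  out
}

# connected zones via union-find over same-level 26-neighbors
oracle_glszm_zones <- function(lev) {
  dims <- dim(lev)
  vox <- which(lev > 0, arr.ind = TRUE)
  n <- nrow(vox)
  if (n == 0) return(matrix(0, 0, 2))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  key <- vox[, 1] + dims[1] * (vox[, 2] - 1 + dims[2] * (vox[, 3] - 1))
  index <- setNames(seq_len(n), key)
  for (a in seq_len(n)) {
    for (p in all_neighbors(vox[a, ], dims)) {
      if (lev[p[1], p[2], p[3]] == lev[vox[a, , drop = FALSE]]) {
        k <- p[1] + dims[1] * (p[2] - 1 + dims[2] * (p[3] - 1))
        b <- index[[as.character(k)]]
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  tab <- table(roots)
  cbind(level = vapply(as.integer(names(tab)), function(r) {
    lev[vox[r, , drop = FALSE]]
  }, 1L), size = as.integer(tab))
}

oracle_glszm_features <- function(zones, np, n_levels) {
  nz <- nrow(zones)
  lev <- zones[, 1]; siz <- zones[, 2]
  glev <- numeric(n_levels)
  for (z in seq_len(nz)) glev[lev[z]] <- glev[lev[z]] + 1
  sizes <- sort(unique(siz))
  gsize <- vapply(sizes, function(s) sum(siz == s), 1.0)
  mug <- mean(lev); mus <- mean(siz)
  pj <- numeric(0)
  for (l in unique(lev)) for (s in unique(siz)) {
    c0 <- sum(lev == l & siz == s)
    if (c0 > 0) pj <- c(pj, c0 / nz)
  }
  ent <- function(v) -sum(v * log2(v))
  c(
    glszm_SmallAreaEmphasis = mean(1 / siz^2),
    glszm_LargeAreaEmphasis = mean(siz^2),
    glszm_GrayLevelNonUniformity = sum(glev^2) / nz,
    glszm_GrayLevelNonUniformityNormalized = sum(glev^2) / nz^2,
    glszm_SizeZoneNonUniformity = sum(gsize^2) / nz,
    glszm_SizeZoneNonUniformityNormalized = sum(gsize^2) / nz^2,
    glszm_ZonePercentage = nz / np,
    glszm_GrayLevelVariance = mean((lev - mug)^2),
    glszm_ZoneVariance = mean((siz - mus)^2),
    glszm_ZoneEntropy = ent(pj),
    glszm_LowGrayLevelZoneEmphasis = mean(1 / lev^2),
    glszm_HighGrayLevelZoneEmphasis = mean(lev^2),
    glszm_SmallAreaLowGrayLevelEmphasis = mean(1 / (lev^2 * siz^2)),
    glszm_SmallAreaHighGrayLevelEmphasis = mean(lev^2 / siz^2),
    glszm_LargeAreaLowGrayLevelEmphasis = mean(siz^2 / lev^2),
    glszm_LargeAreaHighGrayLevelEmphasis = mean(lev^2 * siz^2)
  )
}

oracle_ngtdm_counts <- function(lev) {
  dims <- dim(lev)
  n_levels <- max(lev)
  n_i <- numeric(n_levels); s_i <- numeric(n_levels)
  vox <- which(lev > 0, arr.ind = TRUE)
  for (a in seq_len(nrow(vox))) {
    g <- lev[vox[a, , drop = FALSE]]
    nb <- numeric(0)
    for (p in all_neighbors(vox[a, ], dims)) {
      v <- lev[p[1], p[2], p[3]]
      if (v > 0) nb <- c(nb, v)
    }
    if (length(nb) == 0) next
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  cbind(n_i, s_i)
}

oracle_gldm_matrix <- function(lev, alpha) {
  dims <- dim(lev)
  n_levels <- max(lev)
  D <- matrix(0, n_levels, 27)
  vox <- which(lev > 0, arr.ind = TRUE)
  for (a in seq_len(nrow(vox))) {
    g <- lev[vox[a, , drop = FALSE]]
    dep <- 0
    for (p in all_neighbors(vox[a, ], dims)) {
      v <- lev[p[1], p[2], p[3]]
      if (v > 0 && abs(v - g) <= alpha) dep <- dep + 1
    }
    D[g, dep + 1] <- D[g, dep + 1] + 1
  }
  D
}

oracle_ring <- function(mask, spacing, margin) {
  dims <- dim(mask)
  ring <- array(FALSE, dims)
  tum <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  for (b in seq_len(nrow(bg))) {
    dmin <- Inf
    for (t in seq_len(nrow(tum))) {
      d2 <- sum(((bg[b, ] - tum[t, ]) * spacing)^2)
      if (d2 < dmin) dmin <- d2
    }
    if (dmin <= margin^2) ring[bg[b, 1], bg[b, 2], bg[b, 3]] <- TRUE
  }
  ring
}

oracle_ngtdm_features <- function(cs) {
  n_i <- cs[, 1]; s_i <- cs[, 2]
  N <- sum(n_i)
  p <- n_i / N
  act <- which(p > 0)
  ngp <- length(act)
  den <- sum(p * s_i)
  coarse <- if (den > 0) min(1 / den, 1e6) else 1e6
  contrast <- 0; busy_den <- 0; cmplx <- 0; str_num <- 0
  for (i in act) for (j in act) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    cmplx <- cmplx + abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
    str_num <- str_num + (p[i] + p[j]) * (i - j)^2
  }
  contrast <- if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(s_i) / N else 0
  c(
    ngtdm_Coarseness = coarse,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = if (busy_den > 0) sum(p * s_i) / busy_den else 0,
    ngtdm_Complexity = cmplx / N,
    ngtdm_Strength = if (sum(s_i) > 0) str_num / sum(s_i) else 0
  )
}

oracle_gldm_features <- function(D) {
  nz <- sum(D)
  Ng <- nrow(D); Nd <- ncol(D)
  mug <- 0; mud <- 0
  for (i in 1:Ng) for (j in 1:Nd) {
    mug <- mug + i * D[i, j] / nz
    mud <- mud + j * D[i, j] / nz
  }
  out <- c(SmallDependenceEmphasis = 0, LargeDependenceEmphasis = 0,
           GrayLevelNonUniformity = sum(rowSums(D)^2) / nz,
           DependenceNonUniformity = sum(colSums(D)^2) / nz,
           DependenceNonUniformityNormalized = sum(colSums(D)^2) / nz^2,
           GrayLevelVariance = 0, DependenceVariance = 0,
           DependenceEntropy = 0, LowGrayLevelEmphasis = 0,
           HighGrayLevelEmphasis = 0, SmallDependenceLowGrayLevelEmphasis = 0,
           SmallDependenceHighGrayLevelEmphasis = 0,
           LargeDependenceLowGrayLevelEmphasis = 0,
           LargeDependenceHighGrayLevelEmphasis = 0)
  for (i in 1:Ng) for (j in 1:Nd) {
    d <- D[i, j]
    p <- d / nz
    out["SmallDependenceEmphasis"] <- out["SmallDependenceEmphasis"] + d / j^2
    out["LargeDependenceEmphasis"] <- out["LargeDependenceEmphasis"] + d * j^2
    out["GrayLevelVariance"] <- out["GrayLevelVariance"] + (i - mug)^2 * p
    out["DependenceVariance"] <- out["DependenceVariance"] + (j - mud)^2 * p
    if (p > 0) out["DependenceEntropy"] <- out["DependenceEntropy"] - p * log2(p)
    out["LowGrayLevelEmphasis"] <- out["LowGrayLevelEmphasis"] + d / i^2
    out["HighGrayLevelEmphasis"] <- out["HighGrayLevelEmphasis"] + d * i^2
    out["SmallDependenceLowGrayLevelEmphasis"] <-
      out["SmallDependenceLowGrayLevelEmphasis"] + d / (i^2 * j^2)
    out["SmallDependenceHighGrayLevelEmphasis"] <-
      out["SmallDependenceHighGrayLevelEmphasis"] + d * i^2 / j^2
    out["LargeDependenceLowGrayLevelEmphasis"] <-
      out["LargeDependenceLowGrayLevelEmphasis"] + d * j^2 / i^2
    out["LargeDependenceHighGrayLevelEmphasis"] <-
      out["LargeDependenceHighGrayLevelEmphasis"] + d * i^2 * j^2
  }
  for (nm in c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
               "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
               "SmallDependenceLowGrayLevelEmphasis",
               "SmallDependenceHighGrayLevelEmphasis",
               "LargeDependenceLowGrayLevelEmphasis",
               "LargeDependenceHighGrayLevelEmphasis")) {
    out[nm] <- out[nm] / nz
  }
  names(out) <- paste0("gldm_", names(out))
  out
}

# trapezoidal ROC integration (independent AUC oracle)
trapezoid_auc <- function(scores, labels) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  fpr <- vapply(cuts, function(ct) mean(scores[labels == 0] >= ct), 1.0)
  tpr <- vapply(cuts, function(ct) mean(scores[labels == 1] >= ct), 1.0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
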