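#' Phantom cohort specification
#'
#' Describes a synthetic NSCLC-like cohort: ellipsoidal tumors embedded in a
#' noisy lung-like background, with per-label texture effects that can be
#' implanted independently inside the tumor and in a 3 mm peritumoral shell,
#' plus clinical covariates and binary therapy-response labels
#' (EGFR / Del19 / L858R / T790M / PDL1).
#'
#' Texture inside each compartment is a Gaussian random field: white noise
#' smoothed with a per-patient Gaussian kernel (correlation length `rho`) and
#' scaled to a per-patient amplitude `tau`. A texture shift of `s` for a
#' label moves the population mean of both `tau` and `rho` by `s` between-
#' patient standard deviations for positive patients, so an effect size of
#' 1.5 separates the texture-generating parameters by 1.5 SD.
#'
#' Default label prevalences follow the pooled clinical frequencies reported
#' for NSCLC EGFR-TKI/ICI response modeling (EGFR 38.5%, 19Del 19.1%, L858R
#' 14.9%, T790M 9.2%, PD-1/PD-L1 47.1%). When the canonical five labels are
#' used, Del19 and L858R are drawn as mutually exclusive subtypes of EGFR+
#' and T790M conditionally on EGFR+, which preserves the marginal
#' prevalences; other label sets are drawn independently.
#'
#' @param n_patients number of patients.
#' @param image_shape integer voxel counts per axis.
#' @param voxel_spacing_mm voxel spacing (mm) per axis.
#' @param tumor_radius_range_mm interval of mean tumor radii (mm).
#' @param label_prevalences named vector of label prevalences in `[0, 1]`.
#' @param intratumoral_texture_shift,peritumoral_texture_shift named per-label
#'   effect sizes (SD units) applied to the texture-generating parameters in
#'   the tumor interior / the 3 mm shell; a scalar is recycled to all labels.
#' @param clinical_effect named per-label log-odds-scale association between
#'   labels and the clinical covariates (0 = covariates independent of
#'   labels); scalar recycled.
#' @param noise_sd background HU noise standard deviation.
#' @param rng_seed integer seed; the cohort is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(n_patients = 4, rng_seed = 7)
#' cohort <- generate_cohort(spec)
#' cohort$clinical
#' @export
phantom_spec <- function(n_patients,
                         image_shape = c(36L, 36L, 30L),
                         voxel_spacing_mm = c(1.25, 1.25, 1.25),
                         tumor_radius_range_mm = c(5, 8),
                         label_prevalences = c(EGFR = 0.385, Del19 = 0.191,
                                               L858R = 0.149, T790M = 0.092,
                                               PDL1 = 0.471),
                         intratumoral_texture_shift = 0,
                         peritumoral_texture_shift = 0,
                         clinical_effect = 0,
                         noise_sd = 20,
                         rng_seed = 1L) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1)
  if (length(image_shape) != 3L || any(image_shape < 4)) {
    abort("`image_shape` must be 3 voxel counts >= 4")
  }
  if (any(voxel_spacing_mm <= 0)) abort("voxel spacing must be positive")
  if (is.null(names(label_prevalences)) || any(names(label_prevalences) == "")) {
    abort("`label_prevalences` must be a named vector")
  }
  if (any(label_prevalences < 0 | label_prevalences > 1)) {
    abort("all label prevalences must lie in [0, 1]")
  }
  half_extent <- min(image_shape * voxel_spacing_mm) / 2
  if (any(tumor_radius_range_mm <= 0) ||
      max(tumor_radius_range_mm) >= half_extent) {
    abort(sprintf(
      "tumor radii must be positive and smaller than half the image extent (%.1f mm)",
      half_extent
    ))
  }
  labs <- names(label_prevalences)
  recycle <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- setNames(rep(as.numeric(x), length(labs)), labs)
    }
    x <- x[labs]
    x[is.na(x)] <- 0
    names(x) <- labs
    if (!all(is.finite(x))) abort(sprintf("`%s` must be finite", what))
    x
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      image_shape = as.integer(image_shape),
      voxel_spacing_mm = as.numeric(voxel_spacing_mm),
      tumor_radius_range_mm = as.numeric(sort(tumor_radius_range_mm)),
      label_prevalences = label_prevalences,
      intratumoral_texture_shift =
        recycle(intratumoral_texture_shift, "intratumoral_texture_shift"),
      peritumoral_texture_shift =
        recycle(peritumoral_texture_shift, "peritumoral_texture_shift"),
      clinical_effect = recycle(clinical_effect, "clinical_effect"),
      noise_sd = as.numeric(noise_sd),
      rng_seed = as.integer(rng_seed)
    ),
    class = "phantom_spec"
  )
}

# population parameters of the texture-generating Gaussian fields
.texture_pop <- list(
  tumor = list(mean_hu = 30, tau0 = 60, tau_sd = 12, rho0 = 1.1, rho_sd = 0.25),
  shell = list(mean_hu = -350, tau0 = 45, tau_sd = 10, rho0 = 1.0, rho_sd = 0.25)
)

# Separable Gaussian smoothing of a 3D array (truncated kernel, edge
# renormalization); sigma in voxels, may be 0 (identity).
gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0.05) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  for (axis in seq_len(3L)) {
    if (dim(arr)[axis] > 1L) arr <- filter_axis(arr, k, axis, normalize = TRUE)
  }
  arr
}

# Apply a 1D kernel along one axis of a 3D array via banded matrix products;
# `normalize = TRUE` renormalizes the truncated kernel near edges.
filter_axis <- function(arr, k, axis, normalize = FALSE) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    idx <- seq_len(n)
    tgt <- idx + off
    ok <- tgt >= 1L & tgt <= n
    K[cbind(idx[ok], tgt[ok])] <- k[off + r + 1L]
  }
  if (normalize) K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  res <- K %*% m
  aperm(array(res, d[perm]), order(perm))
}

# draw one correlated texture field on the bounding box of `idx` voxels
texture_field <- function(dims, tau, rho) {
  f <- array(rnorm(prod(dims)), dims)
  f <- gauss_smooth3(f, rho)
  s <- sd(f)
  if (s < 1e-12) s <- 1
  f / s * tau
}

draw_labels <- function(n, prev) {
  labs <- names(prev)
  canonical <- c("EGFR", "Del19", "L858R", "T790M", "PDL1")
  out <- matrix(0L, n, length(labs), dimnames = list(NULL, labs))
  hier <- setequal(labs, canonical) &&
    prev["Del19"] + prev["L858R"] <= prev["EGFR"] &&
    prev["T790M"] <= prev["EGFR"] && prev["EGFR"] > 0
  if (hier) {
    egfr <- rbinom(n, 1L, prev["EGFR"])
    q19 <- prev["Del19"] / prev["EGFR"]
    qL <- prev["L858R"] / prev["EGFR"]
    sub <- runif(n)
    out[, "EGFR"] <- egfr
    out[, "Del19"] <- as.integer(egfr == 1L & sub < q19)
    out[, "L858R"] <- as.integer(egfr == 1L & sub >= q19 & sub < q19 + qL)
    out[, "T790M"] <- as.integer(egfr == 1L &
                                   rbinom(n, 1L, prev["T790M"] / prev["EGFR"]) == 1L)
    out[, "PDL1"] <- rbinom(n, 1L, prev["PDL1"])
  } else {
    for (l in labs) out[, l] <- rbinom(n, 1L, prev[l])
  }
  out
}

draw_clinical <- function(n, latent) {
  loc_p <- c(RUL = 0.30, RML = 0.09, RLL = 0.175, LUL = 0.30, LLL = 0.135)
  tibble(
    age = round(62 + 6 * latent + rnorm(n, 0, 10.8)),
    gender = ifelse(runif(n) < 0.63, "male", "female"),
    smoking = ifelse(runif(n) < plogis(qlogis(0.50) + 1.2 * latent),
                     "smoker", "nonsmoker"),
    tumor_location = sample(names(loc_p), n, replace = TRUE, prob = loc_p),
    lvi = as.integer(runif(n) < plogis(qlogis(0.40) + 1.2 * latent)),
    pi = as.integer(runif(n) < plogis(qlogis(0.65) + 1.0 * latent)),
    t_stage = ifelse(runif(n) < plogis(qlogis(0.30) + 1.2 * latent),
                     "T4", sample(c("T1", "T2", "T3"), n, replace = TRUE))
  )
}

#' Generate a synthetic phantom cohort
#'
#' Draws, deterministically from `spec$rng_seed`, one CT-like volume and
#' tumor mask per patient plus clinical covariates and binary labels. Tumors
#' are random ellipsoids; label-dependent texture is implanted in the tumor
#' interior and, independently, in the shell up to 3 mm outside the tumor
#' boundary, so intratumoral and peritumoral signal can be controlled
#' separately. Intensities are rounded to integer HU (CT convention, and the
#' canonical 16-bit serialization used for encryption).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `synthetic_cohort`: a list with `volumes`
#'   (list of [image_volume()]), `masks` (list of logical arrays on the same
#'   grids), `clinical` (tibble), `labels` (tibble of 0/1 columns) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n_patients
    dims <- spec$image_shape
    sp <- spec$voxel_spacing_mm
    labels <- draw_labels(n, spec$label_prevalences)
    shift_in <- as.numeric(labels %*% spec$intratumoral_texture_shift)
    shift_out <- as.numeric(labels %*% spec$peritumoral_texture_shift)
    latent <- as.numeric(labels %*% spec$clinical_effect)

    volumes <- vector("list", n)
    masks <- vector("list", n)
    centers_mm <- (dims * sp) / 2
    for (p in seq_len(n)) {
      r0 <- runif(1, spec$tumor_radius_range_mm[1], spec$tumor_radius_range_mm[2])
      axes <- r0 * runif(3, 0.8, 1.2)
      axes <- pmin(axes, dims * sp / 2 - sp) # keep the ellipsoid inside
      center <- centers_mm + runif(3, -0.06, 0.06) * dims * sp
      co <- lapply(1:3, function(a) ((seq_len(dims[a]) - 0.5) * sp[a] - center[a]) / axes[a])
      mask <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`) <= 1
      if (!any(mask)) { # degenerate draw: force the center voxel
        mask[ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)] <- TRUE
      }
      img <- array(-780 + rnorm(prod(dims), 0, spec$noise_sd), dims)

      pop <- .texture_pop$tumor
      tau <- max(5, pop$tau0 + pop$tau_sd * (rnorm(1) + shift_in[p]))
      rho <- max(0.3, pop$rho0 + pop$rho_sd * (rnorm(1) + shift_in[p]))
      bb <- mask_bbox(mask, pad = 0L)
      field <- texture_field(bb$dims, tau, rho)
      sub <- img[bb$i, bb$j, bb$k]
      msub <- mask[bb$i, bb$j, bb$k]
      sub[msub] <- pop$mean_hu + field[msub]
      img[bb$i, bb$j, bb$k] <- sub

      shell <- array(.ring_mask(mask, dims, sp, 3.0), dims)
      if (any(shell)) {
        pop <- .texture_pop$shell
        tau <- max(5, pop$tau0 + pop$tau_sd * (rnorm(1) + shift_out[p]))
        rho <- max(0.3, pop$rho0 + pop$rho_sd * (rnorm(1) + shift_out[p]))
        bb <- mask_bbox(shell, pad = 0L)
        field <- texture_field(bb$dims, tau, rho)
        sub <- img[bb$i, bb$j, bb$k]
        msub <- shell[bb$i, bb$j, bb$k]
        sub[msub] <- pop$mean_hu + field[msub]
        img[bb$i, bb$j, bb$k] <- sub
      }
      img <- round(pmin(pmax(img, -1024), 3071)) # clamp to the 12-bit HU range
      volumes[[p]] <- image_volume(img, sp)
      masks[[p]] <- mask
    }

    ids <- sprintf("P%04d", seq_len(n))
    clinical <- dplyr::bind_cols(tibble(patient_id = ids), draw_clinical(n, latent))
    labels_tbl <- dplyr::bind_cols(tibble(patient_id = ids), as_tibble(labels))
    structure(
      list(volumes = volumes, masks = masks, clinical = clinical,
           labels = labels_tbl, spec = spec),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %s voxels @ %s mm, labels: %s\n",
    length(x$volumes), paste(x$spec$image_shape, collapse = "x"),
    paste(signif(x$spec$voxel_spacing_mm, 3), collapse = "x"),
    paste(names(x$spec$label_prevalences), collapse = ", ")
  ))
  invisible(x)
}

# bounding box (index ranges) of a mask, padded and clipped to the grid
mask_bbox <- function(mask, pad = 0L) {
  w <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, min(w[, a]) - pad)
    hi <- min(d[a], max(w[, a]) + pad)
    lo:hi
  })
  list(i = rng[[1]], j = rng[[2]], k = rng[[3]],
       dims = vapply(rng, length, 1L))
}

subset_cohort <- function(cohort, idx) {
  structure(
    list(volumes = cohort$volumes[idx], masks = cohort$masks[idx],
         clinical = cohort$clinical[idx, , drop = FALSE],
         labels = cohort$labels[idx, , drop = FALSE],
         spec = cohort$spec),
    class = "synthetic_cohort"
  )
}

#' Stratified train/test split of a cohort
#'
#' Splits a cohort into disjoint, exhaustive training and test subsets while
#' preserving the prevalence of `stratify_on` within one patient per
#' stratum. The training size is `floor(train_fraction * n)`, apportioned
#' across strata by largest remainder (so 506 patients at fraction 0.6
#' split 303/203).
#'
#' @param cohort a `synthetic_cohort`.
#' @param train_fraction fraction in (0, 1).
#' @param stratify_on label column name to stratify on.
#' @param seed integer seed controlling the assignment.
#' @return a list with elements `train` and `test`, both `synthetic_cohort`.
#' @export
split_cohort <- function(cohort, train_fraction, stratify_on, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1")
  }
  y <- cohort$labels[[stratify_on]]
  if (is.null(y)) abort(sprintf("no label column `%s`", stratify_on))
  strata <- split(seq_along(y), y)
  small <- names(strata)[vapply(strata, length, 1L) < 2L]
  if (length(small)) {
    abort(sprintf("stratum `%s = %s` has fewer than 2 members",
                  stratify_on, paste(small, collapse = ", ")))
  }
  n <- length(y)
  n_train <- floor(train_fraction * n + 1e-9)
  target <- vapply(strata, function(s) train_fraction * length(s), 1.0)
  base <- floor(target + 1e-9)
  rem <- n_train - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  } else if (rem < 0) {
    drop <- order(target - base)[seq_len(-rem)]
    base[drop] <- base[drop] - 1L
  }
  with_seed(seed, {
    train_idx <- sort(unlist(Map(function(s, k) {
      if (k <= 0) integer(0) else sample(s, k)
    }, strata, base), use.names = FALSE))
  })
  list(train = subset_cohort(cohort, train_idx),
       test = subset_cohort(cohort, setdiff(seq_len(n), train_idx)))
}

#' Write a cohort to disk
#'
#' Writes per-patient NIfTI volumes and masks, the clinical table and label
#' table as CSV, and a JSON manifest recording the generating spec.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- cohort$clinical$patient_id
  for (p in seq_along(ids)) {
    write_volume_nifti(cohort$volumes[[p]],
                       file.path(dir, paste0(ids[p], "_image.nii.gz")))
    write_mask_nifti(cohort$masks[[p]], cohort$volumes[[p]]$spacing_mm,
                     file.path(dir, paste0(ids[p], "_mask.nii.gz")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  manifest <- cohort$spec
  class(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
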