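#' Feature extraction configuration
#'
#' @param discretization a [discretization_config()]; the default fixed
#'   25 HU bin width is the de facto CT radiomics choice.
#' @param wavelet logical: also extract every intensity-based family from
#'   each one-level wavelet sub-band (shape excluded)?
#' @param gldm_alpha GLDM dependence tolerance.
#' @param min_voxels minimum in-mask voxel count per region.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(discretization = discretization_config(),
                              wavelet = TRUE, gldm_alpha = 0L,
                              min_voxels = 10L) {
  stopifnot(inherits(discretization, "discretization_config"))
  structure(
    list(discretization = discretization, wavelet = isTRUE(wavelet),
         gldm_alpha = as.integer(gldm_alpha),
         min_voxels = as.integer(min_voxels)),
    class = "extraction_config"
  )
}

# All intensity-based families for one (possibly filtered) image.
intensity_families <- function(arr, mask, cfg, voxel_volume) {
  dz <- discretize_volume(arr, mask, cfg$discretization)
  c(
    first_order_features(arr[mask], cfg$discretization, voxel_volume),
    glcm_features(dz$levels, dz$n_levels),
    glrlm_features(dz$levels, dz$n_levels),
    glszm_features(dz$levels, dz$n_levels),
    ngtdm_features(dz$levels, dz$n_levels),
    gldm_features(dz$levels, dz$n_levels, cfg$gldm_alpha)
  )
}

#' Extract radiomic features from one region
#'
#' Shape (14), first-order (19), GLCM (24), GLRLM (16), GLSZM (16), NGTDM
#' (5) and GLDM (14) features from the original image — 108 values — plus,
#' when `cfg$wavelet` is on, the 94 intensity-based features from each
#' wavelet sub-band. Output ordering is deterministic.
#'
#' @param image an [image_volume()].
#' @param mask logical mask on the same grid.
#' @param cfg an [extraction_config()].
#' @param region_tag label recorded in the output (`roi2d`, `roi3d`, ...).
#' @return a tibble with columns `region`, `image_filter`, `family`,
#'   `feature`, `value`.
#' @export
extract_region_features <- function(image, mask, cfg = extraction_config(),
                                    region_tag = "roi3d") {
  vec <- region_feature_vector(image, mask, cfg, region_tag)
  nm <- names(vec)
  us <- regexpr("_", nm, fixed = TRUE)
  filter_tag <- substr(nm, 1, us - 1)
  feature <- substr(nm, us + 1, nchar(nm))
  tibble(
    region = region_tag,
    image_filter = filter_tag,
    family = sub("_.*$", "", feature),
    feature = feature,
    value = unname(vec)
  )
}

# fast path: named vector `<filter>_<family>_<Feature>` for one region
region_feature_vector <- function(image, mask, cfg, region_tag) {
  arr <- as_array3d(image)
  mask <- check_mask(mask, arr, require_nonempty = FALSE)
  if (sum(mask) < cfg$min_voxels) {
    abort(sprintf("region `%s` has %d voxels, below the minimum of %d",
                  region_tag, sum(mask), cfg$min_voxels))
  }
  spacing <- image$spacing_mm
  voxvol <- prod(spacing)
  parts <- list(
    original = c(shape_features(mask, spacing),
                 intensity_families(arr, mask, cfg, voxvol))
  )
  if (cfg$wavelet) {
    subs <- wavelet_subbands(arr)
    for (nm in names(subs)) {
      parts[[paste0("wavelet.", nm)]] <-
        intensity_families(subs[[nm]], mask, cfg, voxvol)
    }
  }
  out <- unlist(parts, use.names = FALSE)
  names(out) <- unlist(lapply(names(parts), function(tag) {
    paste(tag, names(parts[[tag]]), sep = "_")
  }), use.names = FALSE)
  out
}

tidy_features <- function(values, region, filter_tag) {
  nm <- names(values)
  tibble(
    region = region,
    image_filter = filter_tag,
    family = sub("_.*$", "", nm),
    feature = nm,
    value = unname(values)
  )
}

#' Extract features from all three regions of an ROI bundle
#'
#' Runs [extract_region_features()] on the 2D slice, the 3D tumor and the
#' peritumoral region of a bundle. When `key` is supplied the regions are
#' first encrypted and then decrypted in memory before extraction —
#' mirroring a secure two-step workflow where only ciphertext leaves the
#' acquisition site — which, the round trip being bit-exact, yields
#' identical features.
#'
#' @param bundle an `roi_bundle` from [build_roi_bundle()].
#' @param cfg an [extraction_config()].
#' @param key optional AES-256 key enabling the encrypt/decrypt round trip.
#' @return a tidy tibble of features for the three regions.
#' @export
extract_all <- function(bundle, cfg = extraction_config(), key = NULL) {
  stopifnot(inherits(bundle, "roi_bundle"))
  out <- lapply(c("roi2d", "roi3d", "peritumoral"), function(region) {
    r <- bundle[[region]]
    img <- r$image
    if (!is.null(key)) {
      img <- decrypt_roi(encrypt_roi(img, key), key)
    }
    extract_region_features(img, r$mask, cfg, region_tag = region)
  })
  dplyr::bind_rows(out)
}

#' Extract a cohort-level feature table
#'
#' Builds the ROI bundle for every patient, extracts all features and
#' returns the wide modeling table (one row per patient, one column per
#' `region_filter_family_Feature`). No value is missing after extraction.
#'
#' @param cohort a `synthetic_cohort`.
#' @param cfg an [extraction_config()].
#' @param key optional AES-256 key: encrypt/decrypt each region in memory.
#' @param margin_mm,peritumoral_mode forwarded to [build_roi_bundle()].
#' @return a wide tibble with `patient_id` plus feature columns.
#' @export
extract_cohort <- function(cohort, cfg = extraction_config(), key = NULL,
                           margin_mm = 3,
                           peritumoral_mode = "shell3d") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ids <- cohort$clinical$patient_id
  rows <- vector("list", length(ids))
  for (p in seq_along(ids)) {
    bundle <- build_roi_bundle(cohort$volumes[[p]], cohort$masks[[p]],
                               margin_mm = margin_mm,
                               peritumoral_mode = peritumoral_mode)
    vecs <- lapply(c("roi2d", "roi3d", "peritumoral"), function(region) {
      r <- bundle[[region]]
      img <- r$image
      if (!is.null(key)) img <- decrypt_roi(encrypt_roi(img, key), key)
      v <- region_feature_vector(img, r$mask, cfg, region)
      names(v) <- paste(region, names(v), sep = "_")
      v
    })
    rows[[p]] <- unlist(vecs)
  }
  mat <- do.call(rbind, rows)
  stopifnot(!anyNA(mat))
  dplyr::bind_cols(tibble(patient_id = ids), as_tibble(mat))
}

#' Record the exact extraction configuration as JSON
#'
#' Provenance sidecar for a feature table: discretization mode and
#' parameters, wavelet setting, GLDM tolerance and the minimum region size.
#'
#' @param cfg an [extraction_config()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_extraction_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "extraction_config"))
  obj <- list(
    discretization = unclass(cfg$discretization),
    wavelet = cfg$wavelet,
    gldm_alpha = cfg$gldm_alpha,
    min_voxels = cfg$min_voxels
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write feature tables to CSV
#'
#' `write_features_tidy` stores the long format (patient, region, filter,
#' family, feature, value); `write_features_wide` the modeling matrix.
#'
#' @param features a tibble from [extract_all()] (tidy, with a `patient_id`
#'   column added) or [extract_cohort()] (wide).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_tidy <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_tidy
#' @export
write_features_wide <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
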