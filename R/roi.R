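#' Select the axial slice with the largest tumor area
#'
#' Returns the (1-based) index of the axial slice (third array axis) with
#' the most foreground voxels; ties are broken by the lowest index.
#'
#' @param mask logical 3D array (non-empty).
#' @return integer slice index.
#' @examples
#' m <- array(FALSE, c(3, 3, 4)); m[1:2, 1:2, 2] <- TRUE; m[1, 1, 3] <- TRUE
#' select_largest_slice(m)
#' @export
select_largest_slice <- function(mask) {
  mask <- check_mask(mask)
  areas <- apply(mask, 3L, sum)
  as.integer(which.max(areas))
}

#' Peritumoral ring mask
#'
#' All background voxels whose center lies within `margin_mm` (Euclidean
#' distance in physical mm, honoring anisotropic spacing) of any tumor voxel
#' center, excluding the tumor itself; the ring is clipped at image borders.
#'
#' @param mask logical 3D tumor mask.
#' @param spacing_mm voxel spacing (mm).
#' @param margin_mm positive margin (default 3 mm).
#' @return logical 3D array, disjoint from `mask`.
#' @export
make_peritumoral_mask <- function(mask, spacing_mm, margin_mm = 3) {
  mask <- check_mask(mask)
  if (length(spacing_mm) == 2L) spacing_mm <- c(spacing_mm, 1)
  if (!is.numeric(margin_mm) || margin_mm <= 0) {
    abort("`margin_mm` must be positive")
  }
  ring <- array(.ring_mask(mask, dim(mask), as.numeric(spacing_mm),
                           as.numeric(margin_mm)), dim(mask))
  if (!any(ring)) {
    abort("peritumoral ring is empty (margin smaller than voxel spacing, or ring entirely outside the image)")
  }
  ring
}

#' Resample an image (and optional mask) to a new voxel spacing
#'
#' Intensities are interpolated trilinearly; masks use nearest-neighbor
#' interpolation on the same grid. The new grid has
#' `round(dim * spacing / target)` voxels per axis (at least 1), so the
#' physical extent is preserved to within one voxel. Voxel centers of both
#' grids share the same physical frame (center of voxel `i` at
#' `(i - 0.5) * spacing`).
#'
#' @param volume an [image_volume()] (or 2D/3D array with `spacing_mm`).
#' @param target_spacing_mm new spacing (length 1 is recycled to all axes;
#'   length 2 keeps the third axis spacing unchanged).
#' @param mask optional logical array on the same grid.
#' @return a list with `image` (an [image_volume()]) and, when `mask` was
#'   given, the resampled logical `mask`.
#' @export
resample_volume <- function(volume, target_spacing_mm, mask = NULL) {
  arr <- as_array3d(volume)
  spacing <- if (inherits(volume, "image_volume")) volume$spacing_mm else {
    abort("`volume` must be an image_volume (spacing is required)")
  }
  if (length(target_spacing_mm) == 1L) target_spacing_mm <- rep(target_spacing_mm, 3)
  if (length(target_spacing_mm) == 2L) {
    target_spacing_mm <- c(target_spacing_mm, spacing[3])
  }
  if (!all(is.finite(target_spacing_mm)) || any(target_spacing_mm <= 0)) {
    abort("target spacing must be positive and finite")
  }
  d <- dim(arr)
  nd <- pmax(1L, as.integer(round(d * spacing / target_spacing_mm)))
  if (identical(as.numeric(target_spacing_mm), as.numeric(spacing))) {
    out <- list(image = image_volume(arr, spacing))
    if (!is.null(mask)) out$mask <- check_mask(mask, arr, require_nonempty = FALSE)
    return(out)
  }
  # separable interpolation: one small weight matrix per axis
  ax <- lapply(1:3, function(a) {
    x <- ((seq_len(nd[a]) - 0.5) * target_spacing_mm[a]) / spacing[a] + 0.5
    pmin(pmax(x, 1), d[a])
  })
  lin_w <- function(x, n) {
    lo <- floor(x)
    hi <- pmin(lo + 1, n)
    fr <- x - lo
    W <- matrix(0, length(x), n)
    W[cbind(seq_along(x), lo)] <- W[cbind(seq_along(x), lo)] + (1 - fr)
    W[cbind(seq_along(x), hi)] <- W[cbind(seq_along(x), hi)] + fr
    W
  }
  nn_w <- function(x, n) {
    W <- matrix(0, length(x), n)
    W[cbind(seq_along(x), pmin(pmax(round(x), 1), n))] <- 1
    W
  }
  apply_axis <- function(a3, W, axis) {
    dd <- dim(a3)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a3, perm), nrow = dd[axis])
    res <- W %*% m
    aperm(array(res, c(nrow(W), dd[perm][-1])), order(perm))
  }
  img <- arr
  for (a in 1:3) img <- apply_axis(img, lin_w(ax[[a]], d[a]), a)
  out <- list(image = image_volume(img, target_spacing_mm))
  if (!is.null(mask)) {
    mask <- check_mask(mask, arr, require_nonempty = FALSE)
    m <- mask * 1
    for (a in 1:3) m <- apply_axis(m, nn_w(ax[[a]], d[a]), a)
    out$mask <- array(m > 0.5, nd)
  }
  out
}

#' Build the three analysis regions from a volume and tumor mask
#'
#' Derives the package's three regions of interest: the largest-area axial
#' slice (resampled to `planar_spacing_mm` in-plane), the full 3D tumor and
#' the peritumoral ring within `margin_mm` of the tumor boundary (both
#' resampled to `iso_spacing_mm` isotropic). By default the peritumoral
#' region is a 3D shell derived from the 3D mask; `peritumoral_mode =
#' "ring2d"` instead builds a planar ring around the selected slice.
#' For speed, the 3D regions are cropped to the mask bounding box (plus a
#' pad) before resampling.
#'
#' @param volume an [image_volume()].
#' @param mask logical tumor mask on the same grid.
#' @param margin_mm peritumoral margin (default 3 mm).
#' @param planar_spacing_mm in-plane spacing of the 2D region (default 0.8).
#' @param iso_spacing_mm isotropic spacing of the 3D regions (default 1.0).
#' @param peritumoral_mode `"shell3d"` (default) or `"ring2d"`.
#' @return An object of class `roi_bundle`: list with `roi2d`, `roi3d`,
#'   `peritumoral` (each a list of `image`, `mask`), `slice_index`,
#'   `margin_mm` and `peritumoral_mode`.
#' @export
build_roi_bundle <- function(volume, mask, margin_mm = 3,
                             planar_spacing_mm = 0.8, iso_spacing_mm = 1.0,
                             peritumoral_mode = c("shell3d", "ring2d")) {
  peritumoral_mode <- match.arg(peritumoral_mode)
  arr <- as_array3d(volume)
  mask <- check_mask(mask, arr)
  spacing <- volume$spacing_mm
  si <- select_largest_slice(mask)

  slice_vol <- image_volume(arr[, , si, drop = FALSE], spacing)
  r2 <- resample_volume(slice_vol, c(planar_spacing_mm, planar_spacing_mm),
                        mask = mask[, , si, drop = FALSE])

  bb <- mask_bbox(mask, pad = 2L)
  crop_vol <- image_volume(arr[bb$i, bb$j, bb$k, drop = FALSE], spacing)
  r3 <- resample_volume(crop_vol, iso_spacing_mm,
                        mask = mask[bb$i, bb$j, bb$k, drop = FALSE])

  if (peritumoral_mode == "shell3d") {
    ring <- make_peritumoral_mask(mask, spacing, margin_mm)
    ring_target <- iso_spacing_mm
  } else {
    ring_slice <- make_peritumoral_mask(mask[, , si, drop = FALSE],
                                        spacing, margin_mm)
    ring <- array(FALSE, dim(mask))
    ring[, , si] <- ring_slice
    ring_target <- c(iso_spacing_mm, iso_spacing_mm) # planar, slice kept
  }
  bbr <- mask_bbox(ring, pad = 2L)
  if (peritumoral_mode == "ring2d") bbr$k <- si
  ring_vol <- image_volume(arr[bbr$i, bbr$j, bbr$k, drop = FALSE], spacing)
  rp <- resample_volume(ring_vol, ring_target,
                        mask = ring[bbr$i, bbr$j, bbr$k, drop = FALSE])
  fix_empty <- function(r, src_mask) {
    # nearest-neighbor downsampling can in principle drop a very thin mask;
    # fall back to marking the voxel nearest the source mask centroid
    if (!any(r$mask)) {
      ctr <- round(colMeans(which(src_mask, arr.ind = TRUE)) *
                     dim(r$mask) / dim(src_mask))
      ctr <- pmin(pmax(ctr, 1), dim(r$mask))
      r$mask[ctr[1], ctr[2], ctr[3]] <- TRUE
    }
    r
  }
  r2 <- fix_empty(r2, mask[, , si, drop = FALSE])
  r3 <- fix_empty(r3, mask)
  rp <- fix_empty(rp, ring)

  structure(
    list(
      roi2d = list(image = r2$image, mask = r2$mask),
      roi3d = list(image = r3$image, mask = r3$mask),
      peritumoral = list(image = rp$image, mask = rp$mask),
      slice_index = si,
      margin_mm = margin_mm,
      peritumoral_mode = peritumoral_mode
    ),
    class = "roi_bundle"
  )
}

#' @export
print.roi_bundle <- function(x, ...) {
  n <- function(r) sum(r$mask)
  cat(sprintf(
    "<roi_bundle> slice %d, margin %.1f mm (%s); mask voxels: 2D %d, 3D %d, peritumoral %d\n",
    x$slice_index, x$margin_mm, x$peritumoral_mode,
    n(x$roi2d), n(x$roi3d), n(x$peritumoral)
  ))
  invisible(x)
}

#' Write an ROI bundle to disk
#'
#' One NIfTI image/mask pair per region plus a JSON sidecar recording the
#' slice index, margin and spacings.
#'
#' @param bundle an `roi_bundle`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_roi_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (region in c("roi2d", "roi3d", "peritumoral")) {
    r <- bundle[[region]]
    write_volume_nifti(r$image, file.path(dir, paste0(region, "_image.nii.gz")))
    write_mask_nifti(r$mask, r$image$spacing_mm,
                     file.path(dir, paste0(region, "_mask.nii.gz")))
  }
  sidecar <- list(
    slice_index = bundle$slice_index,
    margin_mm = bundle$margin_mm,
    peritumoral_mode = bundle$peritumoral_mode,
    spacing_mm = lapply(bundle[c("roi2d", "roi3d", "peritumoral")],
                        function(r) r$image$spacing_mm)
  )
  jsonlite::write_json(sidecar, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Strip identifying columns from a clinical table
#'
#' Retains only the modeling covariates (age, gender, smoking,
#' tumor_location, lvi, pi, t_stage) and any therapy-response label columns
#' (EGFR, Del19, L858R, T790M, PDL1); every other column — names,
#' identifiers, dates — is dropped. A pure allow-list function: retained
#' columns pass through unmodified.
#'
#' @param table a data frame.
#' @return a tibble with only allow-listed columns, in schema order.
#' @export
anonymize_clinical <- function(table) {
  covars <- c("age", "gender", "smoking", "tumor_location", "lvi", "pi",
              "t_stage")
  labels <- c("EGFR", "Del19", "L858R", "T790M", "PDL1")
  missing <- setdiff(covars, names(table))
  if (length(missing)) {
    abort(sprintf("mandatory clinical covariates missing: %s",
                  paste(missing, collapse = ", ")))
  }
  keep <- c(covars, intersect(labels, names(table)))
  as_tibble(table[, keep, drop = FALSE])
}
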