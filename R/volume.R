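#' Image volume container
#'
#' A minimal in-memory representation of a (CT-like) image volume: a 3D
#' numeric array of Hounsfield-unit intensities together with its voxel
#' spacing and physical origin. Planar images are represented as volumes
#' with a singleton third dimension, so every routine in the package can
#' treat 2D and 3D regions uniformly. All indices in this package are
#' 1-based (R convention); axial slices run along the third array axis.
#'
#' @param data numeric array (2D or 3D) of finite intensities. Matrices are
#'   promoted to single-slice volumes.
#' @param spacing_mm numeric voxel spacing per axis in mm (length 2 or 3,
#'   strictly positive). A planar spacing is completed with a unit third
#'   component.
#' @param origin physical coordinates (mm) of the first voxel's center.
#' @return An object of class `image_volume` with fields `data`,
#'   `spacing_mm` and `origin`.
#' @examples
#' vol <- image_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(1, 1, 2.5))
#' dim(vol$data)
#' @export
image_volume <- function(data, spacing_mm, origin = c(0, 0, 0)) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 2D matrix or a 3D array")
  }
  if (!all(is.finite(data))) abort("intensities must all be finite")
  if (length(spacing_mm) == 2L) spacing_mm <- c(spacing_mm, 1)
  if (length(spacing_mm) != 3L || !all(is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be 3 strictly positive finite values")
  }
  if (length(origin) != 3L || !all(is.finite(origin))) {
    abort("`origin` must be 3 finite values")
  }
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm),
         origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

# Coerce an array / matrix / image_volume to a plain 3D array.
as_array3d <- function(x) {
  if (inherits(x, "image_volume")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort("expected an image_volume, matrix or 3D array")
  }
  x
}

# Validate a segmentation mask against its companion volume grid.
check_mask <- function(mask, volume = NULL, require_nonempty = TRUE) {
  mask <- as_array3d(mask)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) abort("mask must be binary")
    mask <- array(mask > 0, dim(mask))
  }
  if (!is.null(volume) && !identical(dim(mask), dim(as_array3d(volume)))) {
    abort("mask and volume must share the same grid")
  }
  if (require_nonempty && !any(mask)) abort("mask has no foreground voxels")
  mask
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] keeping
#' the package's `image_volume` container in sync with on-disk voxel spacing.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume an [image_volume()] (or a logical mask array for
#'   `write_mask_nifti`, stored as 0/1 integers).
#' @return `read_volume_nifti` returns an [image_volume()];
#'   the writers return `path` invisibly.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  image_volume(array(as.numeric(img), dim(img)[1:3]), spacing[1:3])
}

#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(volume, path) {
  arr <- as_array3d(volume)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume_nifti
#' @param mask logical 3D array.
#' @param spacing_mm voxel spacing of `mask`.
#' @export
write_mask_nifti <- function(mask, spacing_mm, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
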