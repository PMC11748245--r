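#' Shape features of a segmentation mask (14 features)
#'
#' Geometry of the tumor mask in physical units. Volume and surface area
#' come from a watertight marching-tetrahedra mesh of the binary mask
#' (iso-level 0.5, vertices at voxel centers); `VoxelVolume` is the voxel
#' count times the voxel volume. Axis lengths derive from the principal
#' components of the voxel-center coordinates (`4 * sqrt(eigenvalue)`, the
#' IBSI convention); maximum diameters are the largest pairwise distances
#' between surface-voxel centers overall and within axial / coronal /
#' sagittal planes. Planar (single-slice) masks are treated as a slab of
#' one voxel thickness so the same 14 definitions apply to the 2D region.
#' Degenerate eigenvalue ratios (point-like masks) return 1.
#'
#' @param mask logical 2D/3D mask.
#' @param spacing_mm voxel spacing (mm).
#' @return named numeric vector of 14 features (prefix `shape_`).
#' @export
shape_features <- function(mask, spacing_mm) {
  mask <- check_mask(mask)
  if (length(spacing_mm) == 2L) spacing_mm <- c(spacing_mm, 1)
  spacing_mm <- as.numeric(spacing_mm)
  nvox <- sum(mask)
  voxvol <- prod(spacing_mm)
  # iso-surface of a lightly smoothed indicator; flooring mask voxels just
  # above the iso level keeps thin structures from vanishing
  field <- pmax(gauss_smooth3(mask * 1, 0.9), mask * 0.501)
  mv <- .mesh_area_volume(field, dim(mask), spacing_mm)
  area <- mv[1]
  vol <- mv[2]
  diam <- .max_diameters(mask, dim(mask), spacing_mm)

  co <- which(mask, arr.ind = TRUE)
  co <- sweep(co, 2, spacing_mm, `*`)
  if (nrow(co) > 1L) {
    ev <- sort(eigen(stats::cov(co), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else {
    ev <- c(0, 0, 0)
  }
  axis_len <- 4 * sqrt(ev)
  ratio <- function(num, den) if (den > 1e-12) sqrt(num / den) else 1
  sphericity <- if (area > 0) (36 * pi * vol^2)^(1 / 3) / area else 1

  c(
    shape_MeshVolume = vol,
    shape_VoxelVolume = nvox * voxvol,
    shape_SurfaceArea = area,
    shape_SurfaceVolumeRatio = if (vol > 0) area / vol else 0,
    shape_Sphericity = sphericity,
    shape_Maximum3DDiameter = diam[1],
    shape_Maximum2DDiameterSlice = diam[2],
    shape_Maximum2DDiameterColumn = diam[3],
    shape_Maximum2DDiameterRow = diam[4],
    shape_MajorAxisLength = axis_len[1],
    shape_MinorAxisLength = axis_len[2],
    shape_LeastAxisLength = axis_len[3],
    shape_Elongation = ratio(ev[2], ev[1]),
    shape_Flatness = ratio(ev[3], ev[1])
  )
}
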