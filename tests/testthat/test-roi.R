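test_that("largest-slice selection follows areas with lowest-index ties", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 2] <- TRUE
  m[1:3, 1:3, 3] <- TRUE # 9 voxels
  m[1:2, 1:4, 4] <- TRUE # 8 voxels (area pattern 0, 1, 9, 8)
  expect_identical(select_largest_slice(m), 3L)

  single <- array(FALSE, c(3, 3, 5))
  single[2, 2, 4] <- TRUE
  expect_identical(select_largest_slice(single), 4L)

  tie <- array(FALSE, c(4, 4, 3))
  tie[1:2, 1:2, 1] <- TRUE # 4
  tie[1:3, 1:3, 2] <- TRUE # 9
  tie[2:4, 2:4, 3] <- TRUE # 9 -> tie broken to slice 2
  expect_identical(select_largest_slice(tie), 2L)
  # exhaustive scan confirms the tie rule
  areas <- apply(tie, 3, sum)
  expect_identical(select_largest_slice(tie),
                   which(areas == max(areas))[1])

  expect_error(select_largest_slice(array(FALSE, c(3, 3, 3))), "foreground")
})

test_that("slice selection is equivariant under axial reordering", {
  set.seed(21)
  m <- array(runif(6 * 6 * 5) < 0.3, c(6, 6, 5))
  m[2:4, 2:4, 3] <- TRUE
  perm <- c(4L, 1L, 3L, 5L, 2L)
  mp <- m[, , perm]
  si <- select_largest_slice(m)
  expect_identical(perm[select_largest_slice(mp)], si)
})

test_that("peritumoral ring equals brute-force distance thresholding", {
  # single seed voxel, isotropic 1 mm, margin 3 mm
  m <- array(FALSE, c(9, 9, 9))
  m[5, 5, 5] <- TRUE
  ring <- make_peritumoral_mask(m, c(1, 1, 1), 3)
  oracle <- oracle_ring(m, c(1, 1, 1), 3)
  expect_identical(ring, oracle)
  # count matches the enumerated ball minus the seed
  expect_identical(sum(ring), sum(oracle))

  # anisotropic spacing, random blob
  set.seed(31)
  m2 <- array(FALSE, c(10, 8, 6))
  m2[3:6, 3:5, 2:4] <- runif(4 * 3 * 3) < 0.7
  if (!any(m2)) m2[4, 4, 3] <- TRUE
  ring2 <- make_peritumoral_mask(m2, c(1, 1.5, 2.5), 3)
  expect_identical(ring2, oracle_ring(m2, c(1, 1.5, 2.5), 3))
})

test_that("ring is disjoint from the tumor and clipped at borders", {
  set.seed(32)
  for (r in 1:15) {
    m <- array(FALSE, c(8, 8, 8))
    ctr <- sample(2:7, 3, TRUE)
    m[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)] <-
      array(runif(27) < 0.8, c(3, 3, 3))
    if (!any(m)) m[ctr[1], ctr[2], ctr[3]] <- TRUE
    ring <- make_peritumoral_mask(m, c(1, 1, 1), 2)
    expect_false(any(ring & m))
  }
})

test_that("sub-voxel margins yield the empty-ring error path", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  expect_error(make_peritumoral_mask(m, c(1, 1, 1), 0.4), "empty")
  expect_error(make_peritumoral_mask(m, c(1, 1, 1), 0), "positive")
})

test_that("resampling: identity, constancy and extent arithmetic", {
  set.seed(41)
  arr <- array(rnorm(10 * 12 * 8), c(10, 12, 8))
  vol <- image_volume(arr, c(2, 2, 2))
  # identity spacing returns voxelwise-identical data
  same <- resample_volume(vol, c(2, 2, 2))
  expect_identical(same$image$data, arr)
  # constant image stays constant under any spacing
  kvol <- image_volume(array(4, c(6, 6, 6)), c(2, 2, 2))
  k2 <- resample_volume(kvol, 1.3)
  expect_true(all(abs(k2$image$data - 4) < 1e-12))
  # 2 mm -> 1 mm doubles grid dimensions (within one voxel)
  up <- resample_volume(vol, 1)
  expect_true(all(abs(dim(up$image$data) - 2 * dim(arr)) <= 1))
  expect_error(resample_volume(vol, c(NA, 1, 1)), "positive")
})

test_that("mask resampling round trip approximately preserves volume", {
  # 8+ mm blob: a -> b -> a changes voxel volume by < 5%
  co <- lapply(1:3, function(a) (seq_len(16) - 8.5))
  m <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`) <= 5^2
  vol <- image_volume(array(0, dim(m)), c(1, 1, 1))
  down <- resample_volume(vol, 1.6, mask = m)
  vol2 <- down$image
  back <- resample_volume(vol2, 1, mask = down$mask)
  v0 <- sum(m)
  v2 <- sum(back$mask)
  expect_lt(abs(v2 - v0) / v0, 0.05)
})

test_that("ROI bundles carry the three regions with correct provenance", {
  co <- generate_cohort(phantom_spec(n_patients = 1, rng_seed = 13))
  vol <- co$volumes[[1]]
  mask <- co$masks[[1]]
  b <- build_roi_bundle(vol, mask)
  expect_s3_class(b, "roi_bundle")
  expect_identical(b$margin_mm, 3)
  expect_identical(b$peritumoral_mode, "shell3d")
  expect_identical(b$slice_index, select_largest_slice(mask))
  expect_equal(b$roi2d$image$spacing_mm[1:2], c(0.8, 0.8))
  expect_equal(b$roi3d$image$spacing_mm, c(1, 1, 1))
  expect_equal(b$peritumoral$image$spacing_mm, c(1, 1, 1))
  expect_identical(dim(b$roi2d$mask)[3], 1L)
  # the 2D region is the largest-area slice of the source mask
  areas <- apply(mask, 3, sum)
  expect_identical(areas[b$slice_index], max(areas))
  # ring mode 2d also works
  b2 <- build_roi_bundle(vol, mask, peritumoral_mode = "ring2d")
  expect_identical(dim(b2$peritumoral$mask)[3], 1L)
})

test_that("a spherical phantom selects its equatorial slice", {
  co <- lapply(1:3, function(a) seq_len(21) - 11)
  m <- outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`) <= 6^2
  vol <- image_volume(array(rnorm(21^3), c(21, 21, 21)), c(1, 1, 1))
  b <- build_roi_bundle(vol, m)
  expect_identical(b$slice_index, 11L) # z = 0 plane
})

test_that("bundle invariants hold across random phantoms", {
  co <- generate_cohort(phantom_spec(n_patients = 8, rng_seed = 17))
  for (p in 1:8) {
    b <- build_roi_bundle(co$volumes[[p]], co$masks[[p]])
    for (region in c("roi2d", "roi3d", "peritumoral")) {
      r <- b[[region]]
      expect_identical(dim(r$mask), dim(r$image$data))
      expect_gt(sum(r$mask), 0)
    }
    ring_native <- make_peritumoral_mask(co$masks[[p]],
                                         co$volumes[[p]]$spacing_mm, 3)
    expect_false(any(ring_native & co$masks[[p]]))
  }
})

test_that("roi bundle writes NIfTI files plus a JSON sidecar", {
  co <- generate_cohort(phantom_spec(n_patients = 1, rng_seed = 19))
  b <- build_roi_bundle(co$volumes[[1]], co$masks[[1]])
  dir <- tempfile("bundle")
  write_roi_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "roi3d_image.nii.gz")))
  sc <- jsonlite::fromJSON(file.path(dir, "bundle.json"))
  expect_equal(sc$margin_mm, 3)
  expect_equal(sc$slice_index, b$slice_index)
  unlink(dir, recursive = TRUE)
})

test_that("clinical anonymization applies a strict allow-list", {
  co <- generate_cohort(phantom_spec(
    n_patients = 3, image_shape = c(10L, 10L, 8L),
    tumor_radius_range_mm = c(2.5, 3.5), rng_seed = 23
  ))
  tbl <- co$clinical
  tbl$patient_name <- c("a", "b", "c")
  tbl$scan_date <- Sys.Date() + 0:2
  out <- anonymize_clinical(tbl)
  expect_false(any(c("patient_name", "scan_date", "patient_id") %in% names(out)))
  expect_identical(out$age, tbl$age)
  expect_identical(out$gender, tbl$gender)
  # empty table keeps the schema
  empty <- anonymize_clinical(tbl[0, ])
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("age", "smoking", "t_stage") %in% names(empty)))
  expect_error(anonymize_clinical(tbl[, -2]), "missing")
})
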