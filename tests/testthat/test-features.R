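test_that("discretization follows the fixed-bin-width and bin-count rules", {
  cfg <- discretization_config(bin_width = 25)
  d <- discretize(c(0, 25, 50), cfg)
  expect_identical(d$levels, c(1L, 2L, 3L))
  expect_identical(d$n_levels, 3L)
  # constant region collapses to one level
  expect_identical(discretize(rep(7, 10), cfg)$n_levels, 1L)
  # fixed bin count on a uniform ramp fills bins near-evenly
  cfg8 <- discretization_config("fixed_bin_count", bin_count = 8)
  d8 <- discretize(seq(0, 1, length.out = 800), cfg8)
  occ <- tabulate(d8$levels, 8)
  expect_identical(d8$n_levels, 8L)
  expect_true(all(occ >= 90) && all(occ <= 110))
  # resegmentation clips before binning
  cfgr <- discretization_config(bin_width = 10,
                                resegmentation_range = c(0, 50))
  expect_identical(max(discretize(c(-100, 10, 500), cfgr)$levels), 6L)
})

test_that("first-order features match hand computations", {
  cfg <- discretization_config("fixed_bin_count", bin_count = 2)
  f <- first_order_features(c(1, 1, 3, 3), cfg)
  expect_length(f, 19)
  expect_equal(f[["firstorder_Mean"]], 2)
  expect_equal(f[["firstorder_Entropy"]], 1) # two equi-probable levels: 1 bit
  expect_equal(f[["firstorder_Variance"]], 1) # population variance
  expect_equal(f[["firstorder_Range"]], 2)
  expect_equal(f[["firstorder_RootMeanSquared"]], sqrt(5))

  k <- first_order_features(rep(4, 12), discretization_config())
  expect_equal(k[["firstorder_Variance"]], 0)
  expect_equal(k[["firstorder_Entropy"]], 0)
  expect_equal(k[["firstorder_Uniformity"]], 1)
  expect_equal(k[["firstorder_Skewness"]], 0)
  expect_true(all(is.finite(k)))
})

test_that("shape features: voxel volume, digital ball, feature count", {
  single <- array(FALSE, c(3, 3, 3))
  single[2, 2, 2] <- TRUE
  s1 <- shape_features(single, c(1, 1, 1))
  expect_length(s1, 14)
  expect_equal(s1[["shape_VoxelVolume"]], 1)
  expect_true(all(is.finite(s1)))

  # digital ball r = 10 mm: mesh volume and sphericity within 5% of analytic
  n <- 25
  co <- seq_len(n) - (n + 1) / 2
  ball <- outer(outer(co^2, co^2, `+`), co^2, `+`) <= 10^2
  sb <- shape_features(ball, c(1, 1, 1))
  expect_lt(abs(sb[["shape_MeshVolume"]] - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_lt(abs(sb[["shape_Sphericity"]] - 1), 0.05)
  expect_lt(abs(sb[["shape_Maximum3DDiameter"]] - 20) / 20, 0.1)
  # principal-axis convention: 4 * sqrt(lambda) = 4 r / sqrt(5) for a solid ball
  expect_lt(abs(sb[["shape_MajorAxisLength"]] - 4 * 10 / sqrt(5)) / 20, 0.05)
  expect_gt(sb[["shape_Elongation"]], 0.95)
  expect_gt(sb[["shape_Flatness"]], 0.95)
})

test_that("GLCM examples: checkerboard and constant images", {
  # 2-level checkerboard, unit horizontal offset: all mass off-diagonal
  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) + 1L)
  lev <- array(as.integer(cb), c(6, 6, 1))
  f <- glcm_features(lev, 2, offsets = rbind(c(1L, 0L, 0L)))
  expect_equal(f[["glcm_Contrast"]], 1) # every pair differs by exactly 1
  expect_equal(f[["glcm_MaximumProbability"]], 0.5)
  expect_equal(f[["glcm_JointEnergy"]], 0.5)
  M <- encrad:::.glcm_counts(lev, dim(lev), 2L, rbind(c(1L, 0L, 0L)))[, , 1]
  expect_identical(diag(M), c(0, 0))
  expect_identical(M, oracle_glcm_matrix(lev, c(1, 0, 0)))

  k <- array(1L, c(4, 4, 4))
  fk <- glcm_features(k, 1)
  expect_equal(fk[["glcm_JointEnergy"]], 1)
  expect_equal(fk[["glcm_Contrast"]], 0)
  expect_length(fk, 24)
})

test_that("GLRLM hand-enumerated line examples", {
  # constant 1 x N line: one run of length N
  line <- array(1L, c(7, 1, 1))
  f <- glrlm_features(line, 1, directions = rbind(c(1L, 0L, 0L)))
  expect_equal(f[["glrlm_LongRunEmphasis"]], 49)
  expect_equal(f[["glrlm_RunPercentage"]], 1 / 7)
  # strictly alternating line: N runs of length 1
  alt <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
  fa <- glrlm_features(alt, 2, directions = rbind(c(1L, 0L, 0L)))
  expect_equal(fa[["glrlm_ShortRunEmphasis"]], 1)
  expect_equal(fa[["glrlm_RunPercentage"]], 1)
  expect_length(fa, 16)
})

test_that("GLSZM zones match connected-component reasoning", {
  lev <- array(0L, c(6, 6, 1))
  lev[1:3, 1, 1] <- 2L # zone of 3
  lev[5:6, 4:5, 1] <- 2L # zone of 4... separated
  lev[1, 6, 1] <- 1L
  z <- encrad:::.glszm_zones(lev, dim(lev))
  sizes <- sort(z[z[, 1] == 2, 2])
  expect_identical(sizes, c(3L, 4L))
  f <- glszm_features(lev, 2)
  expect_length(f, 16)
  # constant region: a single zone of n voxels
  k <- array(1L, c(3, 3, 2))
  zk <- encrad:::.glszm_zones(k, dim(k))
  expect_identical(nrow(zk), 1L)
  expect_identical(zk[1, 2], 18L)
})

test_that("NGTDM and GLDM degenerate conventions", {
  k <- array(1L, c(4, 4, 1))
  fn <- ngtdm_features(k, 1)
  expect_length(fn, 5)
  expect_equal(fn[["ngtdm_Coarseness"]], 1e6) # defined maximum
  expect_equal(fn[["ngtdm_Contrast"]], 0)
  fd <- gldm_features(k, 1, alpha = 0)
  expect_length(fd, 14)
  # every interior voxel maximally dependent within an 8-neighborhood plane
  D <- encrad:::.gldm_counts(k, dim(k), 1L, 0L)
  expect_equal(sum(D[1, ]), 16)
  expect_equal(D[1, 9], 4) # the four interior voxels have all 8 neighbors
})

test_that("wavelet sub-bands: count, constancy and Parseval factor", {
  k <- array(5, c(8, 8, 8))
  subs <- wavelet_subbands(k)
  expect_length(subs, 8)
  expect_named(subs, c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH"))
  for (nm in setdiff(names(subs), "LLL")) {
    expect_lt(max(abs(subs[[nm]])), 1e-9)
  }
  # orthonormal filters on periodic boundaries: energies sum to 2^3 x input
  set.seed(51)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  sx <- wavelet_subbands(x)
  etot <- sum(vapply(sx, function(s) sum(s^2), 1.0))
  expect_equal(etot, 8 * sum(x^2), tolerance = 1e-8)
  # planar input gives the 4 in-plane sub-bands, Parseval factor 2^2
  pm <- matrix(rnorm(64), 8, 8)
  p <- wavelet_subbands(pm)
  expect_length(p, 4)
  ep <- sum(vapply(p, function(s) sum(s^2), 1.0))
  expect_equal(ep, 4 * sum(pm^2), tolerance = 1e-8)
})

test_that("feature families carry their declared cardinalities per region", {
  co <- generate_cohort(phantom_spec(n_patients = 1, rng_seed = 29))
  b <- build_roi_bundle(co$volumes[[1]], co$masks[[1]])
  f <- extract_all(b, extraction_config(wavelet = FALSE))
  counts <- dplyr::count(f, region, family)
  declared <- c(firstorder = 19L, glcm = 24L, gldm = 14L, glrlm = 16L,
                glszm = 16L, ngtdm = 5L, shape = 14L)
  for (region in c("roi2d", "roi3d", "peritumoral")) {
    sub <- counts[counts$region == region, ]
    expect_identical(setNames(sub$n, sub$family), declared)
  }
  # 108 original-image features per region; deterministic ordering
  expect_identical(nrow(f), 3L * 108L)
  f2 <- extract_all(b, extraction_config(wavelet = FALSE))
  expect_identical(f, f2)
})

test_that("wavelet extraction adds 94 features per sub-band (shape excluded)", {
  co <- generate_cohort(phantom_spec(n_patients = 1, rng_seed = 31))
  b <- build_roi_bundle(co$volumes[[1]], co$masks[[1]])
  f <- extract_all(b, extraction_config(wavelet = TRUE))
  n3d <- sum(f$region == "roi3d")
  expect_identical(n3d, 108L + 8L * 94L)
  n2d <- sum(f$region == "roi2d")
  expect_identical(n2d, 108L + 4L * 94L)
})

test_that("encrypted extraction equals plaintext extraction bit for bit", {
  co <- generate_cohort(phantom_spec(n_patients = 1, rng_seed = 37))
  b <- build_roi_bundle(co$volumes[[1]], co$masks[[1]])
  cfg <- extraction_config(wavelet = FALSE)
  plain <- extract_all(b, cfg)
  enc <- extract_all(b, cfg, key = fixed_key())
  expect_identical(plain$value, enc$value)
})

test_that("fixed-bin-count features are invariant to intensity shifts", {
  set.seed(61)
  arr <- array(rnorm(6^3, 0, 30), c(6, 6, 6))
  mask <- array(runif(6^3) < 0.8, c(6, 6, 6))
  mask[3, 3, 3] <- TRUE
  cfg <- discretization_config("fixed_bin_count", bin_count = 8)
  d1 <- encrad:::discretize_volume(arr, mask, cfg)
  d2 <- encrad:::discretize_volume(arr + 500, mask, cfg)
  expect_identical(d1$levels, d2$levels)
  expect_identical(glcm_features(d1$levels, d1$n_levels),
                   glcm_features(d2$levels, d2$n_levels))
})

test_that("offset-averaged GLCM features are axis-permutation consistent", {
  set.seed(63)
  arr <- array(sample.int(5, 6^3, TRUE), c(6, 6, 6))
  f1 <- glcm_features(arr, 5)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    fp <- glcm_features(aperm(arr, perm), 5)
    expect_lt(max(abs(f1 - fp)), 1e-12)
  }
})

test_that("the extraction config round-trips through its JSON sidecar", {
  cfg <- extraction_config(
    discretization = discretization_config("fixed_bin_count", bin_count = 16),
    wavelet = FALSE, gldm_alpha = 1
  )
  path <- tempfile(fileext = ".json")
  write_extraction_config(cfg, path)
  back <- jsonlite::fromJSON(path)
  expect_identical(back$discretization$mode, "fixed_bin_count")
  expect_identical(back$discretization$bin_count, 16L)
  expect_false(back$wavelet)
  expect_identical(back$gldm_alpha, 1L)
  unlink(path)
})

test_that("regions below the voxel minimum fail with a named error", {
  img <- image_volume(array(rnorm(27), c(3, 3, 3)), c(1, 1, 1))
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  expect_error(
    encrad:::region_feature_vector(img, m, extraction_config(), "roi3d"),
    "roi3d.*below the minimum"
  )
})
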