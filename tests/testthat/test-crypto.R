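test_that("AES-256 core matches the published known-answer vector", {
  # FIPS-197 / SP 800-38A AES-256 single-block vector, run through CBC with a
  # zero IV (equivalent to one ECB block)
  key <- rad_key("603deb1015ca71be2b73aef0857d77811f352c073b6108d72d9810a30914dff4")
  pt <- as.raw(strtoi(substring("6bc1bee22e409f96e93d7e117393172a",
                                seq(1, 31, 2), seq(2, 32, 2)), 16L))
  ct <- encrad:::.aes256_cbc_encrypt(pt, key, as.raw(rep(0, 16)))
  expect_identical(paste(sprintf("%02x", as.integer(ct)), collapse = ""),
                   "f3eed1bdb5d2a03c064b5a7e3db181f8")
})

test_that("CBC chaining agrees with an independent reference implementation", {
  skip_if_not_installed("digest")
  set.seed(101)
  for (len in c(16L, 64L, 1024L)) {
    key <- as.raw(sample(0:255, 32, TRUE))
    iv <- as.raw(sample(0:255, 16, TRUE))
    pt <- as.raw(sample(0:255, len, TRUE))
    ref <- digest::AES(key, mode = "CBC", IV = iv)
    expect_identical(encrad:::.aes256_cbc_encrypt(pt, key, iv),
                     as.raw(ref$encrypt(pt)))
  }
})

test_that("encrypt/decrypt round trip is bit-exact and well-typed", {
  set.seed(7)
  key <- fixed_key()
  vol <- image_volume(array(round(rnorm(10 * 9 * 4, 0, 300)), c(10, 9, 4)),
                      c(1, 1, 2))
  enc <- encrypt_roi(vol, key, iv = as.raw(rep(3, 16)))
  expect_s3_class(enc, "encrypted_roi")
  expect_identical(enc$dtype_tag, "int16")
  expect_identical(length(enc$ciphertext) %% 16L, 0L)
  dec <- decrypt_roi(enc, key)
  expect_identical(dec$data, vol$data)
  expect_identical(dec$spacing_mm, vol$spacing_mm)

  # non-integral intensities round-trip through the float64 path
  volf <- image_volume(array(rnorm(5 * 5 * 2), c(5, 5, 2)), c(1, 1, 1))
  encf <- encrypt_roi(volf, key)
  expect_identical(encf$dtype_tag, "float64")
  expect_identical(decrypt_roi(encf, key)$data, volf$data)
})

test_that("IV handling: fresh random IVs differ, fixed IVs are deterministic", {
  key <- fixed_key()
  arr <- array(round(rnorm(64, 0, 100)), c(8, 8, 1))
  e1 <- encrypt_roi(arr, key)
  e2 <- encrypt_roi(arr, key)
  expect_false(identical(e1$ciphertext, e2$ciphertext))
  iv <- as.raw(rep(9, 16))
  expect_identical(encrypt_roi(arr, key, iv)$ciphertext,
                   encrypt_roi(arr, key, iv)$ciphertext)
})

test_that("a single plaintext bit flip changes all subsequent blocks", {
  key <- fixed_key()
  iv <- as.raw(rep(0, 16))
  pt <- as.raw(rep(17, 160))
  pt2 <- pt
  pt2[33] <- xor(pt2[33], as.raw(1)) # inside block 3
  c1 <- encrad:::.aes256_cbc_encrypt(pt, key, iv)
  c2 <- encrad:::.aes256_cbc_encrypt(pt2, key, iv)
  blocks_equal <- vapply(seq_len(10), function(b) {
    identical(c1[(16 * (b - 1) + 1):(16 * b)], c2[(16 * (b - 1) + 1):(16 * b)])
  }, TRUE)
  expect_true(all(blocks_equal[1:2]))
  expect_false(any(blocks_equal[3:10]))
})

test_that("corrupted input surfaces as explicit errors, never silent garbage", {
  key <- fixed_key()
  arr <- array(round(rnorm(100, 0, 50)), c(10, 10, 1))
  enc <- encrypt_roi(arr, key)
  trunc <- enc
  trunc$ciphertext <- enc$ciphertext[1:(length(enc$ciphertext) - 16)]
  expect_error(decrypt_roi(trunc, key), "size|padding|length")
  wrong <- as.raw(rev(1:32))
  expect_error(decrypt_roi(enc, wrong), "padding|corrupted|size")
  expect_error(encrypt_roi(arr, as.raw(1:5)), "32 bytes")
  expect_error(encrypt_roi(array(c(NaN, 1:7), c(2, 2, 2)), key), "non-finite")
})

test_that("encrypted container files round-trip losslessly", {
  key <- fixed_key()
  vol <- image_volume(array(round(rnorm(60, 0, 400)), c(5, 4, 3)), c(1, 1, 1))
  enc <- encrypt_roi(vol, key, iv = as.raw(1:16))
  path <- tempfile(fileext = ".enc")
  write_encrypted_roi(enc, path)
  back <- read_encrypted_roi(path)
  expect_identical(back$ciphertext, enc$ciphertext)
  expect_identical(back$iv, enc$iv)
  expect_identical(back$shape, enc$shape)
  expect_identical(decrypt_roi(back, key)$data, vol$data)
  unlink(path)
})

test_that("ciphertext bytes are near-uniform (chi-square, 256 bins)", {
  key <- fixed_key()
  set.seed(42)
  fails <- 0L
  n_enc <- 100L
  for (r in seq_len(n_enc)) {
    arr <- array(round(rnorm(12^3, 0, 60)), c(12, 12, 12))
    enc <- encrypt_roi(arr, key)
    counts <- tabulate(as.integer(enc$ciphertext) + 1L, 256L)
    p <- suppressWarnings(stats::chisq.test(counts)$p.value)
    if (p < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, ceiling(0.05 * n_enc))
})

test_that("keys coerce from hex and validate length", {
  k <- rad_key(paste(rep("0f", 32), collapse = ""))
  expect_identical(k, as.raw(rep(15, 32)))
  expect_error(rad_key("zz"), "hex|raw")
  expect_length(rad_key_random(), 32)
  expect_length(rad_iv_random(), 16)
})
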