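#' Keys and initialization vectors
#'
#' `rad_key()` coerces a 32-byte AES-256 key from a raw vector or a 64-char
#' hex string. `rad_key_random()` draws a fresh key, `rad_iv_random()` a
#' fresh 16-byte IV; both use `openssl::rand_bytes()` when the openssl
#' package is installed and fall back to R's RNG otherwise (reproducible but
#' not cryptographically unpredictable — supply externally generated keys
#' for real deployments). Keys are never stored inside encrypted containers.
#'
#' @param x raw vector of length 32 or a 64-character hex string.
#' @return a raw vector (32 bytes for keys, 16 for IVs).
#' @examples
#' key <- rad_key(paste(rep("ab", 32), collapse = ""))
#' length(key)
#' @export
rad_key <- function(x) {
  if (is.raw(x)) {
    if (length(x) != 32L) abort("AES-256 key must be exactly 32 bytes")
    return(x)
  }
  if (is.character(x) && length(x) == 1L && grepl("^[0-9a-fA-F]{64}$", x)) {
    return(as.raw(strtoi(substring(x, seq(1, 63, 2), seq(2, 64, 2)), 16L)))
  }
  abort("key must be 32 raw bytes or a 64-character hex string")
}

rand_raw <- function(n) {
  if (requireNamespace("openssl", quietly = TRUE)) {
    openssl::rand_bytes(n)
  } else {
    as.raw(sample.int(256L, n, replace = TRUE) - 1L)
  }
}

#' @rdname rad_key
#' @export
rad_key_random <- function() rand_raw(32L)

#' @rdname rad_key
#' @export
rad_iv_random <- function() rand_raw(16L)

pkcs7_pad <- function(x) {
  p <- 16L - (length(x) %% 16L)
  c(x, as.raw(rep(p, p)))
}

pkcs7_unpad <- function(x) {
  if (length(x) == 0L || length(x) %% 16L != 0L) {
    abort("decryption failed: ciphertext length invalid")
  }
  p <- as.integer(x[length(x)])
  if (p < 1L || p > 16L ||
      !all(x[(length(x) - p + 1L):length(x)] == as.raw(p))) {
    abort("decryption failed: bad padding (wrong key or corrupted ciphertext)")
  }
  x[seq_len(length(x) - p)]
}

# canonical serialization: little-endian, column-major, dtype-tagged
serialize_payload <- function(arr, dtype_tag) {
  v <- as.vector(arr)
  if (dtype_tag == "int16") {
    writeBin(as.integer(v), raw(), size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), raw(), size = 8L, endian = "little")
  }
}

deserialize_payload <- function(bytes, shape, dtype_tag) {
  n <- prod(shape)
  if (dtype_tag == "int16") {
    if (length(bytes) != 2 * n) abort("decryption failed: payload size mismatch")
    v <- readBin(bytes, what = "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
  } else {
    if (length(bytes) != 8 * n) abort("decryption failed: payload size mismatch")
    v <- readBin(bytes, what = "double", n = n, size = 8L, endian = "little")
  }
  array(as.numeric(v), shape)
}

#' Encrypt a region of interest with AES-256-CBC
#'
#' Serializes the array canonically (little-endian, column-major; integer
#' HU volumes in the signed 16-bit range are stored as int16, anything else
#' as float64), pads with PKCS#7, and encrypts with AES-256 in cipher-block
#' chaining mode: each plaintext block is XOR-ed with the previous
#' ciphertext block (the IV for the first block) before block encryption.
#' A fresh random IV is drawn when none is supplied; the IV is stored in
#' the container (CBC does not require a secret IV).
#'
#' @param x an [image_volume()], matrix or array with finite values.
#' @param key 32-byte key (see [rad_key()]).
#' @param iv optional 16-byte IV; random when `NULL`.
#' @return An object of class `encrypted_roi`: `ciphertext`, `iv`, `shape`,
#'   `dtype_tag`, `spacing_mm`, `pad_len`.
#' @export
encrypt_roi <- function(x, key, iv = NULL) {
  key <- rad_key(key)
  spacing <- if (inherits(x, "image_volume")) x$spacing_mm else c(1, 1, 1)
  arr <- as_array3d(x)
  if (!all(is.finite(arr))) abort("cannot encrypt non-finite intensities")
  int_like <- all(arr == round(arr)) && min(arr) >= -32768 && max(arr) <= 32767
  dtype_tag <- if (int_like) "int16" else "float64"
  if (is.null(iv)) iv <- rad_iv_random()
  if (!is.raw(iv) || length(iv) != 16L) abort("IV must be exactly 16 raw bytes")
  payload <- serialize_payload(arr, dtype_tag)
  padded <- pkcs7_pad(payload)
  structure(
    list(
      ciphertext = .aes256_cbc_encrypt(padded, key, iv),
      iv = iv,
      shape = dim(arr),
      dtype_tag = dtype_tag,
      spacing_mm = spacing,
      pad_len = length(padded) - length(payload)
    ),
    class = "encrypted_roi"
  )
}

#' Decrypt an encrypted ROI
#'
#' Exact inverse of [encrypt_roi()]: the round trip is bit-identical. A
#' wrong key or corrupted ciphertext surfaces as an explicit padding /
#' size error, never as silent garbage. The decrypted array exists only in
#' memory; nothing is written to disk.
#'
#' @param enc an `encrypted_roi`.
#' @param key the 32-byte key used for encryption.
#' @return an [image_volume()] with the original intensities.
#' @export
decrypt_roi <- function(enc, key) {
  stopifnot(inherits(enc, "encrypted_roi"))
  key <- rad_key(key)
  pt <- .aes256_cbc_decrypt(enc$ciphertext, key, enc$iv)
  bytes <- pkcs7_unpad(pt)
  arr <- deserialize_payload(bytes, enc$shape, enc$dtype_tag)
  image_volume(arr, enc$spacing_mm)
}

#' @export
print.encrypted_roi <- function(x, ...) {
  cat(sprintf(
    "<encrypted_roi> %s voxels (%s), %d ciphertext bytes, AES-256-CBC\n",
    paste(x$shape, collapse = "x"), x$dtype_tag, length(x$ciphertext)
  ))
  invisible(x)
}

#' Encrypted-ROI container file
#'
#' A small documented binary format: the magic bytes `ENCR1`, a 4-byte
#' little-endian header length, a JSON header (shape, dtype, spacing, IV as
#' hex, pad length) and the raw ciphertext payload.
#'
#' @param enc an `encrypted_roi`.
#' @param path output file.
#' @return `write_encrypted_roi` returns `path` invisibly;
#'   `read_encrypted_roi` returns the `encrypted_roi`.
#' @export
write_encrypted_roi <- function(enc, path) {
  stopifnot(inherits(enc, "encrypted_roi"))
  hdr <- jsonlite::toJSON(list(
    shape = enc$shape, dtype_tag = enc$dtype_tag,
    spacing_mm = enc$spacing_mm, pad_len = enc$pad_len,
    iv = paste(sprintf("%02x", as.integer(enc$iv)), collapse = "")
  ), auto_unbox = TRUE, digits = NA)
  hdr_raw <- charToRaw(as.character(hdr))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ENCR1"), con)
  writeBin(length(hdr_raw), con, size = 4L, endian = "little")
  writeBin(hdr_raw, con)
  writeBin(enc$ciphertext, con)
  invisible(path)
}

#' @rdname write_encrypted_roi
#' @export
read_encrypted_roi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 5L)
  if (!identical(rawToChar(magic), "ENCR1")) abort("not an ENCR1 container")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  ct <- readBin(con, "raw", file.size(path))
  iv <- as.raw(strtoi(substring(hdr$iv, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  structure(
    list(ciphertext = ct, iv = iv, shape = as.integer(hdr$shape),
         dtype_tag = hdr$dtype_tag, spacing_mm = as.numeric(hdr$spacing_mm),
         pad_len = as.integer(hdr$pad_len)),
    class = "encrypted_roi"
  )
}
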