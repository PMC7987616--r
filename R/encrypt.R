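#' Password-based AES-256 output encryption
#'
#' Encrypts output bytes with AES-256 and authenticates them, so a wrong
#' password or any tampering raises an authentication error — decryption
#' never returns silent garbage.  The scheme is encrypt-then-MAC: a salted,
#' iterated KDF (bcrypt-pbkdf) stretches the password into 64 bytes, the
#' first 32 keying AES-256-CBC and the last 32 keying an HMAC-SHA-256 over
#' the container header and ciphertext.  The container stores a one-byte
#' format version plus the KDF parameters, salt and IV, so the layout can
#' migrate.
#'
#' Container layout (fixed lengths):
#' `magic "EHE1" | version (1) | kdf rounds (4, big-endian) | salt (16) |
#' iv (16) | hmac (32) | ciphertext`.
#'
#' @param data a raw vector (e.g. a serialized CSV).
#' @param password non-empty scalar string.
#' @param rounds KDF iteration count.
#' @param salt,iv normally random; fixable only to test the container
#'   format byte-for-byte.
#' @return `encrypt_raw()`: the container as a raw vector;
#'   `decrypt_raw()`: the original bytes.
#' @export
encrypt_raw <- function(data, password, rounds = 16L,
                        salt = openssl::rand_bytes(16),
                        iv = openssl::rand_bytes(16)) {
  stopifnot(is.raw(data), is.character(password), length(password) == 1, nzchar(password))
  stopifnot(length(salt) == 16, length(iv) == 16)
  keys <- openssl::bcrypt_pbkdf(password, salt, rounds = as.integer(rounds), size = 64L)
  ct <- as.raw(openssl::aes_cbc_encrypt(data, key = keys[1:32], iv = iv))
  header <- c(charToRaw("EHE1"), as.raw(1L),
    writeBin(as.integer(rounds), raw(), size = 4, endian = "big"),
    salt, iv)
  mac <- openssl::sha256(c(header, ct), key = keys[33:64])
  c(header, as.raw(mac), ct)
}

#' @rdname encrypt_raw
#' @param container a raw vector produced by `encrypt_raw()`.
#' @export
decrypt_raw <- function(container, password) {
  stopifnot(is.raw(container))
  hdr_len <- 4 + 1 + 4 + 16 + 16
  if (length(container) < hdr_len + 32 + 16 ||
      !identical(container[1:4], charToRaw("EHE1"))) {
    abort("not a recognisable encrypted container (bad magic or truncated)")
  }
  version <- as.integer(container[5])
  if (version != 1L) abort(paste("unsupported container version:", version))
  rounds <- readBin(container[6:9], "integer", size = 4, endian = "big")
  salt <- container[10:25]
  iv <- container[26:41]
  mac <- container[42:73]
  ct <- container[-seq_len(73)]
  keys <- openssl::bcrypt_pbkdf(password, salt, rounds = rounds, size = 64L)
  expect <- as.raw(openssl::sha256(c(container[seq_len(hdr_len)], ct), key = keys[33:64]))
  if (!identical(as.raw(mac), expect)) {
    abort("authentication failed: wrong password or corrupted container")
  }
  openssl::aes_cbc_decrypt(structure(ct, iv = iv), key = keys[1:32], iv = iv)
}

#' @rdname encrypt_raw
#' @param path file to encrypt; writes `<path>.enc` alongside.
#' @return `encrypt_file()` the container path; `decrypt_file()` the
#'   decrypted output path, invisibly.
#' @export
encrypt_file <- function(path, password) {
  data <- readBin(path, "raw", n = file.info(path)$size)
  out <- paste0(path, ".enc")
  writeBin(encrypt_raw(data, password), out)
  invisible(out)
}

#' @rdname encrypt_raw
#' @param out_path where to write the decrypted bytes.
#' @export
decrypt_file <- function(path, password, out_path = sub("\\.enc$", "", path)) {
  container <- readBin(path, "raw", n = file.info(path)$size)
  writeBin(decrypt_raw(container, password), out_path)
  invisible(out_path)
}
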