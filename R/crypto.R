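# Key pairs, Ethereum-style addresses and sign/verify. Ed25519 via openssl;
# the address is the last 20 bytes of the SHA-256 digest of the raw 32-byte
# public key, rendered as 0x + 40 lowercase hex characters.

#' Generate an Ed25519 key pair
#'
#' With `seed = NULL` the private scalar is drawn from OS entropy. A non-null
#' integer seed derives the scalar deterministically (SHA-256 of a tagged seed
#' string); this path exists so simulations and tests are reproducible, and
#' must not be used for anything security-sensitive.
#'
#' @param seed Integer seed for deterministic key derivation, or `NULL`.
#' @return A `fedchain_keypair`: list with `key` (openssl private key),
#'   `pubkey_hex` (64 hex chars, raw public key) and `address`.
#' @export
keygen <- function(seed = NULL) {
  scalar <- if (is.null(seed)) {
    openssl::rand_bytes(32L)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    openssl::sha256(charToRaw(sprintf("fedchain-ed25519-seed:%.0f", seed)))
  }
  key <- openssl::read_ed25519_key(as.raw(scalar))
  pub <- as.list(key)$pubkey
  pub_hex <- raw_to_hex(as.list(pub)$data)
  structure(
    list(key = key, pubkey_hex = pub_hex, address = address_of(pub_hex)),
    class = "fedchain_keypair"
  )
}

#' @export
print.fedchain_keypair <- function(x, ...) {
  cat("<fedchain keypair> address", short_address(x$address), "\n")
  invisible(x)
}

#' Derive the ledger address of a public key
#'
#' @param public_key Public key as 64 hex characters (raw Ed25519 key bytes)
#'   or an openssl pubkey object.
#' @return Address string matching `^0x[0-9a-f]{40}$`.
#' @export
address_of <- function(public_key) {
  if (inherits(public_key, "pubkey")) {
    public_key <- raw_to_hex(as.list(public_key)$data)
  }
  if (!is.character(public_key) || length(public_key) != 1L ||
      nchar(public_key) != 64L || grepl("[^0-9a-f]", public_key)) {
    stop("malformed public key: expected 64 lowercase hex characters",
         call. = FALSE)
  }
  dg <- as.raw(openssl::sha256(hex_to_raw(public_key)))
  paste0("0x", raw_to_hex(dg[13:32]))
}

#' Short display form of an address
#'
#' Renders `0x5b3d...` style truncation: first five characters, four dots,
#' last five characters.
#'
#' @param address Full `0x...` address.
#' @return Short form, e.g. `"0x5B3....eddC4"`-shaped.
#' @export
short_address <- function(address) {
  stopifnot(is.character(address), nchar(address) >= 10L)
  paste0(substr(address, 1L, 5L), "....",
         substr(address, nchar(address) - 4L, nchar(address)))
}

#' Sign a message
#'
#' @param keypair A `fedchain_keypair`.
#' @param message Raw vector or character scalar (UTF-8 bytes).
#' @return Signature as a hex string.
#' @export
sign_message <- function(keypair, message) {
  stopifnot(inherits(keypair, "fedchain_keypair"))
  if (is.character(message)) message <- charToRaw(paste(message, collapse = ""))
  raw_to_hex(openssl::signature_create(message, key = keypair$key, hash = NULL))
}

#' Verify a signature
#'
#' Returns `FALSE` (never raises) for malformed signatures or keys, so a
#' garbage signature on a transaction is an ordinary rejection, not a crash.
#'
#' @param pubkey_hex Public key as 64 hex characters.
#' @param message Raw vector or character scalar.
#' @param signature_hex Signature hex string.
#' @return Logical scalar.
#' @export
verify_signature <- function(pubkey_hex, message, signature_hex) {
  if (is.character(message)) message <- charToRaw(paste(message, collapse = ""))
  tryCatch({
    pub <- openssl::read_ed25519_pubkey(hex_to_raw(pubkey_hex))
    isTRUE(openssl::signature_verify(message, hex_to_raw(signature_hex),
                                     pubkey = pub, hash = NULL))
  }, error = function(e) FALSE)
}
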