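# Canonical serialization and digests shared by the ledger, contracts and
# attack modules. All hashed material goes through canonical_json() so that a
# byte-identical serialization is reproducible across runs.

#' Canonical JSON serialization
#'
#' Serializes an R list to a canonical JSON string: object keys sorted
#' lexicographically at every depth, no insignificant whitespace, scalars
#' unboxed, UTF-8. Two structurally equal objects always serialize to the
#' same bytes, which is what makes chain hashes and state digests comparable
#' across runs.
#'
#' @param x A (possibly nested) list of scalars, vectors and lists.
#' @return A single JSON string.
#' @export
canonical_json <- function(x) {
  as.character(jsonlite::toJSON(
    canonicalize(x),
    auto_unbox = TRUE, digits = I(15), null = "null", na = "null"
  ))
}

canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) x <- x[order(nm, method = "radix")]
    lapply(x, canonicalize)
  } else {
    x
  }
}

#' SHA-256 digest as lowercase hex
#'
#' @param x A raw vector or a character scalar (taken as UTF-8 bytes).
#' @return 64-character lowercase hex string.
#' @export
sha256_hex <- function(x) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = ""))
  stopifnot(is.raw(x))
  raw_to_hex(as.raw(openssl::sha256(x)))
}

raw_to_hex <- function(r) paste(as.character(r), collapse = "")

hex_to_raw <- function(h) {
  h <- gsub("^0x", "", tolower(h))
  if (nchar(h) %% 2 != 0 || grepl("[^0-9a-f]", h)) {
    stop("not a hex string", call. = FALSE)
  }
  as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))
}
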