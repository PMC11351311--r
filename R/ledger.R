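# Append-only hash-chained transaction log with a local content-addressed
# off-chain store. A single honest sequencer orders transactions by arrival;
# accepted transactions mutate the contract state immediately and are batched
# into blocks by seal_block(). Rejected transactions leave chain, contract
# state and off-chain store byte-identical (revert semantics).

TX_TYPES <- c("REGISTER", "GRANT", "REVOKE", "DATA_WRITE",
              "MODEL_SUBMIT", "AGGREGATE", "REWARD")

GENESIS_PREV_HASH <- strrep("0", 64)

#' Ledger configuration
#'
#' @param performance_floor Minimum accuracy on the public validation split
#'   for a model update to be accepted (contract-level validation check).
#' @param validation_matrix Optional [feature_matrix()] used as the public
#'   validation split; when `NULL`, the performance check is skipped.
#' @return A `ledger_config` list.
#' @export
ledger_config <- function(performance_floor = 0.5, validation_matrix = NULL) {
  stopifnot(performance_floor >= 0, performance_floor <= 1)
  structure(list(performance_floor = performance_floor,
                 validation_matrix = validation_matrix),
            class = "ledger_config")
}

# canonical signing bytes for a transaction (everything except the signature)
tx_signing_string <- function(tx) {
  canonical_json(list(tx_type = tx$tx_type, sender = tx$sender,
                      nonce = tx$nonce, payload = tx$payload))
}

#' Build and sign a transaction
#'
#' @param keypair Sender's `fedchain_keypair`.
#' @param tx_type One of REGISTER, GRANT, REVOKE, DATA_WRITE, MODEL_SUBMIT,
#'   AGGREGATE, REWARD.
#' @param payload Type-specific named list (canonical-JSON serializable).
#' @param nonce Per-sender monotone counter; must be the sender's last
#'   accepted nonce plus one.
#' @return A signed transaction list.
#' @export
make_tx <- function(keypair, tx_type, payload, nonce) {
  tx <- list(tx_type = tx_type, sender = keypair$address,
             nonce = as.integer(nonce), payload = payload)
  tx$signature <- sign_message(keypair, tx_signing_string(tx))
  tx
}

block_hash_of <- function(index, timestamp, prev_hash, tx_list) {
  sha256_hex(canonical_json(list(index = index, timestamp = timestamp,
                                 prev_hash = prev_hash, tx_list = tx_list)))
}

empty_contract_state <- function() {
  list(
    registry = list(),   # address -> list(role, public_key)
    consents = list(),   # owner address -> character vector of grantees
    records = list(),    # owner address -> character vector of content hashes
    round_state = list(current_round = 1L,
                       accepted_updates = list(),  # "round" -> list of refs
                       global_model_hash = list(), # "round" -> hash
                       aggregated = integer(0),
                       rewarded = integer(0)),
    balances = list()    # address -> numeric reward units
  )
}

#' Permissioned hash-chained ledger
#'
#' The central mutable object of the simulation. Construction seals a genesis
#' block containing the admin's self-signed bootstrap registration; from then
#' on every transaction must carry a valid signature from a registered sender
#' and the sender's next nonce, and must be approved by the contract layer
#' (see `contract_validate`). Timestamps are a monotone logical clock so that
#' chains are byte-reproducible.
#'
#' @examples
#' admin <- keygen(seed = 1)
#' led <- Ledger$new(admin)
#' led$verify_chain()
#' @export
Ledger <- R6::R6Class("Ledger",
  public = list(
    #' @field chain List of sealed blocks (element 1 is genesis).
    chain = NULL,
    #' @field pending Accepted transactions awaiting the next seal.
    pending = NULL,
    #' @field state Contract state (registry, consents, records, rounds,
    #'   balances).
    state = NULL,
    #' @field nonces Named list, last accepted nonce per sender.
    nonces = NULL,
    #' @field clock Logical clock used for block timestamps.
    clock = NULL,
    #' @field config A [ledger_config()].
    config = NULL,
    #' @field admin_address Address registered as admin in the genesis block.
    admin_address = NULL,

    #' @description Create a ledger with a genesis block registering `admin_keypair`.
    #' @param admin_keypair The sequencer/admin `fedchain_keypair`.
    #' @param config A [ledger_config()].
    initialize = function(admin_keypair, config = ledger_config()) {
      stopifnot(inherits(admin_keypair, "fedchain_keypair"))
      self$config <- config
      self$admin_address <- admin_keypair$address
      self$state <- empty_contract_state()
      self$nonces <- list()
      self$pending <- list()
      self$chain <- list()
      self$clock <- 0L
      private$store <- new.env(parent = emptyenv())
      boot <- make_tx(admin_keypair, "REGISTER",
                      list(subject_address = admin_keypair$address,
                           public_key = admin_keypair$pubkey_hex,
                           role = "admin"),
                      nonce = 1L)
      self$state$registry[[admin_keypair$address]] <-
        list(role = "admin", public_key = admin_keypair$pubkey_hex)
      self$nonces[[admin_keypair$address]] <- 1L
      self$pending <- list(boot)
      self$seal_block()
      invisible(self)
    },

    #' @description Submit a signed transaction.
    #' @param tx A transaction from [make_tx()].
    #' @param blob Optional raw sidecar blob (record or model bytes) written
    #'   off-chain only if the transaction is accepted.
    #' @return Receipt list: `accepted`, `reason` (`NULL` when accepted) and
    #'   `result` (contract-specific, e.g. `FALSE` for a no-op revoke).
    submit_tx = function(tx, blob = NULL) {
      reject <- function(reason) list(accepted = FALSE, reason = reason,
                                      result = NULL)
      if (!is.list(tx) ||
          !all(c("tx_type", "sender", "nonce", "payload", "signature")
               %in% names(tx))) {
        return(reject("malformed"))
      }
      if (!tx$tx_type %in% TX_TYPES) return(reject("unknown_type"))
      reg <- self$state$registry[[tx$sender]]
      if (!is.null(reg) &&
          !verify_signature(reg$public_key, tx_signing_string(tx),
                            tx$signature)) {
        return(reject("signature_invalid"))
      }
      expected <- (self$nonces[[tx$sender]] %||% 0L) + 1L
      if (!identical(as.integer(tx$nonce), expected)) return(reject("replay"))
      verdict <- contract_validate(self$state, tx, blob, self$config, self)
      if (!verdict$ok) return(reject(verdict$reason))
      # accept: all mutations happen only on this path
      self$state <- verdict$state
      self$nonces[[tx$sender]] <- as.integer(tx$nonce)
      if (isTRUE(verdict$store_blob)) self$put_offchain(blob)
      self$pending[[length(self$pending) + 1L]] <- tx
      list(accepted = TRUE, reason = NULL, result = verdict$result)
    },

    #' @description Seal pending transactions into a new block (possibly empty).
    #' @return The sealed block, invisibly.
    seal_block = function() {
      idx <- length(self$chain)
      prev <- if (idx == 0L) GENESIS_PREV_HASH else
        self$chain[[idx]]$block_hash
      blk <- list(index = idx, timestamp = self$clock,
                  prev_hash = prev, tx_list = self$pending)
      blk$block_hash <- block_hash_of(blk$index, blk$timestamp,
                                      blk$prev_hash, blk$tx_list)
      self$chain[[idx + 1L]] <- blk
      self$pending <- list()
      self$clock <- self$clock + 1L
      invisible(blk)
    },

    #' @description Verify hash linkage and every transaction signature.
    #' @return `TRUE`, or `FALSE` with attribute `"diagnostic"` naming the
    #'   first failing block.
    verify_chain = function() {
      verify_blocks(self$chain)
    },

    #' @description Store a blob in the content-addressed off-chain store.
    #' @param blob Non-empty raw vector.
    #' @return The content hash (SHA-256 hex).
    put_offchain = function(blob) {
      if (!is.raw(blob) || length(blob) == 0L) {
        stop("blob must be a non-empty raw vector", call. = FALSE)
      }
      h <- sha256_hex(blob)
      assign(h, blob, envir = private$store)
      h
    },

    #' @description Fetch a blob by content hash.
    #' @param content_hash SHA-256 hex string.
    #' @return The raw blob; errors if unknown.
    get_offchain = function(content_hash) {
      if (!exists(content_hash, envir = private$store, inherits = FALSE)) {
        stop("content hash not found in off-chain store: ",
             short_address(content_hash), call. = FALSE)
      }
      get(content_hash, envir = private$store, inherits = FALSE)
    },

    #' @description Hashes currently present in the off-chain store.
    #' @return Sorted character vector.
    offchain_hashes = function() {
      sort(ls(private$store))
    },

    #' @description All accepted transactions in chain order (sealed blocks
    #'   first, then the pending pool in arrival order).
    #' @return List of transactions.
    accepted_txs = function() {
      c(do.call(c, lapply(self$chain, function(b) b$tx_list)), self$pending)
    },

    #' @description Filtered audit trail over accepted transactions.
    #' @param sender Optional sender address filter.
    #' @param tx_type Optional type filter.
    #' @param round Optional round filter (matches `payload$round`).
    #' @return List of matching transactions, chain order.
    audit_trail = function(sender = NULL, tx_type = NULL, round = NULL) {
      txs <- self$accepted_txs()
      keep <- vapply(txs, function(tx) {
        (is.null(sender) || identical(tx$sender, sender)) &&
          (is.null(tx_type) || identical(tx$tx_type, tx_type)) &&
          (is.null(round) || identical(as.integer(tx$payload$round %||% -1L),
                                       as.integer(round)))
      }, logical(1))
      txs[keep]
    },

    #' @description Export the chain as JSON lines (one block per line).
    #' @return Character vector of canonical JSON strings.
    export_chain = function() {
      vapply(self$chain, canonical_json, character(1))
    },

    #' @description Digest of the complete observable state: contract state,
    #'   block hashes, pending pool, nonces and off-chain contents. Used to
    #'   prove revert completeness.
    #' @return SHA-256 hex string.
    state_digest = function() {
      sha256_hex(canonical_json(list(
        state = self$state,
        blocks = lapply(self$chain, function(b) b$block_hash),
        pending = lapply(self$pending, tx_signing_string),
        nonces = self$nonces,
        offchain = as.list(self$offchain_hashes())
      )))
    },

    #' @description Compact printout.
    print = function(...) {
      cat(sprintf(
        "<Ledger> %d blocks, %d pending tx, %d registered, round %d\n",
        length(self$chain), length(self$pending),
        length(self$state$registry), self$state$round_state$current_round))
      invisible(self)
    }
  ),
  private = list(store = NULL)
)

#' Verify a list of blocks
#'
#' Standalone verification used both by `Ledger$verify_chain()` and on
#' chains re-imported from a JSON-lines dump: recomputes every block hash,
#' checks the `prev_hash` linkage (genesis must point at 64 zero hex chars),
#' and verifies every transaction signature against the registry replayed
#' from the chain itself (a REGISTER may be self-signed by the subject, which
#' covers the admin bootstrap).
#'
#' @param chain List of block lists.
#' @return `TRUE`, or `FALSE` carrying attribute `"diagnostic"`.
#' @export
verify_blocks <- function(chain) {
  fail <- function(i, why) {
    structure(FALSE, diagnostic = sprintf("block %d: %s", i - 1L, why))
  }
  if (length(chain) == 0L) return(TRUE)
  reg_pub <- list()
  for (i in seq_along(chain)) {
    b <- chain[[i]]
    if (!identical(as.integer(b$index), i - 1L)) return(fail(i, "bad index"))
    expected_prev <- if (i == 1L) GENESIS_PREV_HASH else
      chain[[i - 1L]]$block_hash
    if (!identical(b$prev_hash, expected_prev)) {
      return(fail(i, "prev_hash mismatch"))
    }
    recomputed <- block_hash_of(b$index, b$timestamp, b$prev_hash, b$tx_list)
    if (!identical(recomputed, b$block_hash)) {
      return(fail(i, "block hash mismatch"))
    }
    for (tx in b$tx_list) {
      pub <- reg_pub[[tx$sender]]
      if (is.null(pub) && identical(tx$tx_type, "REGISTER") &&
          identical(tx$payload$subject_address, tx$sender)) {
        pub <- tx$payload$public_key  # self-signed bootstrap registration
      }
      if (is.null(pub) ||
          !verify_signature(pub, tx_signing_string(tx), tx$signature)) {
        return(fail(i, "tx signature invalid"))
      }
      if (identical(tx$tx_type, "REGISTER")) {
        reg_pub[[tx$payload$subject_address]] <- tx$payload$public_key
      }
    }
  }
  TRUE
}

#' Parse a JSON-lines chain dump
#'
#' Inverse of `Ledger$export_chain()`; the result can be fed to
#' [verify_blocks()].
#'
#' @param lines Character vector, one JSON block per line.
#' @return List of block lists.
#' @export
import_chain <- function(lines) {
  lapply(lines, function(ln) {
    jsonlite::fromJSON(ln, simplifyVector = FALSE, simplifyDataFrame = FALSE)
  })
}
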