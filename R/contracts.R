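# Smart-contract state machines, executed when a transaction is submitted.
# contract_validate() takes the current state and returns either a rejection
# reason or a fully-built candidate state; Ledger$submit_tx swaps the state
# only on acceptance, which gives revert semantics for free.

CONTRACT_ROLES <- c("owner", "producer", "consumer", "fl_client", "admin")

# dispatch table entry: list(ok, reason, state, result, store_blob)
contract_validate <- function(state, tx, blob, config, ledger) {
  ok <- function(state, result = TRUE, store_blob = FALSE) {
    list(ok = TRUE, reason = NULL, state = state, result = result,
         store_blob = store_blob)
  }
  bad <- function(reason) list(ok = FALSE, reason = reason)
  sender_reg <- state$registry[[tx$sender]]
  p <- tx$payload

  switch(tx$tx_type,
    REGISTER = {
      if (is.null(p$role) || !p$role %in% CONTRACT_ROLES) {
        return(bad("invalid_role"))
      }
      authorized <- (!is.null(sender_reg) && sender_reg$role == "admin") ||
        (!is.null(sender_reg) && sender_reg$role == "owner" &&
           p$role %in% c("producer", "consumer"))
      if (!authorized) return(bad("unauthorized"))
      if (!is.null(state$registry[[p$subject_address]])) {
        return(bad("already_registered"))
      }
      if (!is.character(p$public_key) || nchar(p$public_key) != 64L) {
        return(bad("invalid_key"))
      }
      state$registry[[p$subject_address]] <-
        list(role = p$role, public_key = p$public_key)
      ok(state)
    },
    GRANT = {
      if (is.null(sender_reg) || sender_reg$role != "owner") {
        return(bad("unauthorized"))
      }
      if (is.null(state$registry[[p$grantee]])) return(bad("unknown_grantee"))
      state$consents[[tx$sender]] <-
        sort(union(state$consents[[tx$sender]] %||% character(0), p$grantee))
      ok(state)
    },
    REVOKE = {
      if (is.null(sender_reg) || sender_reg$role != "owner") {
        return(bad("unauthorized"))
      }
      had <- p$grantee %in% (state$consents[[tx$sender]] %||% character(0))
      if (had) {
        state$consents[[tx$sender]] <-
          setdiff(state$consents[[tx$sender]], p$grantee)
      }
      # a no-op revoke is recorded but reports FALSE
      ok(state, result = had)
    },
    DATA_WRITE = {
      if (is.null(sender_reg)) return(bad("unauthorized"))
      if (sender_reg$role != "producer") return(bad("forbidden_role"))
      if (!state_has_access(state, tx$sender, p$owner)) {
        return(bad("unauthorized"))
      }
      if (!is.raw(blob) || length(blob) == 0L ||
          !identical(sha256_hex(blob), p$record_hash)) {
        return(bad("blob_invalid"))
      }
      state$records[[p$owner]] <-
        c(state$records[[p$owner]] %||% character(0), p$record_hash)
      ok(state, store_blob = TRUE)
    },
    MODEL_SUBMIT = {
      if (is.null(sender_reg) || sender_reg$role != "fl_client") {
        return(bad("unauthorized_client"))
      }
      rs <- state$round_state
      if (!identical(as.integer(p$round), rs$current_round)) {
        return(bad("wrong_round"))
      }
      key <- as.character(p$round)
      prior <- vapply(rs$accepted_updates[[key]] %||% list(),
                      function(u) u$client, character(1))
      if (tx$sender %in% prior) return(bad("duplicate_update"))
      if (is.null(p$n_local) || p$n_local < 1) return(bad("format_invalid"))
      if (!is.raw(blob) || length(blob) == 0L ||
          !identical(sha256_hex(blob), p$model_hash)) {
        return(bad("format_invalid"))
      }
      model <- tryCatch(deserialize_model(blob), error = function(e) NULL)
      if (is.null(model)) return(bad("format_invalid"))
      if (!is.null(config$validation_matrix)) {
        acc <- evaluate_model(model, config$validation_matrix)$accuracy
        if (acc < config$performance_floor) {
          return(bad("performance_below_floor"))
        }
      }
      state$round_state$accepted_updates[[key]] <-
        c(rs$accepted_updates[[key]] %||% list(),
          list(list(client = tx$sender, model_hash = p$model_hash,
                    n_local = as.integer(p$n_local),
                    reported_metrics = p$reported_metrics)))
      ok(state, store_blob = TRUE)
    },
    AGGREGATE = {
      if (is.null(sender_reg) || sender_reg$role != "admin") {
        return(bad("unauthorized"))
      }
      rs <- state$round_state
      rnd <- as.integer(p$round)
      if (rnd %in% rs$aggregated) return(bad("already_aggregated"))
      if (!identical(rnd, rs$current_round)) return(bad("wrong_round"))
      updates <- rs$accepted_updates[[as.character(rnd)]] %||% list()
      if (length(updates) == 0L) return(bad("empty_round"))
      if (!is.raw(blob) || length(blob) == 0L ||
          !identical(sha256_hex(blob), p$global_model_hash)) {
        return(bad("format_invalid"))
      }
      state$round_state$global_model_hash[[as.character(rnd)]] <-
        p$global_model_hash
      state$round_state$aggregated <- c(rs$aggregated, rnd)
      state$round_state$current_round <- rs$current_round + 1L
      ok(state, store_blob = TRUE)
    },
    REWARD = {
      if (is.null(sender_reg) || sender_reg$role != "admin") {
        return(bad("unauthorized"))
      }
      rs <- state$round_state
      rnd <- as.integer(p$round)
      if (!rnd %in% rs$aggregated) return(bad("not_aggregated"))
      if (rnd %in% rs$rewarded) return(bad("already_rewarded"))
      if (is.null(p$amount_each) || p$amount_each < 0) {
        return(bad("invalid_amount"))
      }
      for (u in rs$accepted_updates[[as.character(rnd)]]) {
        state$balances[[u$client]] <-
          (state$balances[[u$client]] %||% 0) + p$amount_each
      }
      state$round_state$rewarded <- c(rs$rewarded, rnd)
      ok(state)
    },
    bad("unknown_type")
  )
}

state_has_access <- function(state, requester, owner) {
  if (is.null(state$registry[[requester]])) return(FALSE)
  identical(requester, owner) ||
    requester %in% (state$consents[[owner]] %||% character(0))
}

# ---- convenience submission API (builds nonce, signs, submits) -------------

ledger_next_nonce <- function(ledger, address) {
  (ledger$nonces[[address]] %||% 0L) + 1L
}

submit_signed <- function(ledger, keypair, tx_type, payload, blob = NULL) {
  tx <- make_tx(keypair, tx_type, payload,
                nonce = ledger_next_nonce(ledger, keypair$address))
  ledger$submit_tx(tx, blob = blob)
}

#' Register a participant
#'
#' Admin may register any role; a registered data owner may register
#' producers/consumers for their own data. Duplicate addresses are rejected.
#'
#' @param ledger A [Ledger] object.
#' @param sender_keypair Keypair of the registering party.
#' @param subject_keypair Keypair (or at least address + public key) of the
#'   party being registered.
#' @param role One of `owner`, `producer`, `consumer`, `fl_client`, `admin`.
#' @return Submission receipt.
#' @export
ct_register <- function(ledger, sender_keypair, subject_keypair, role) {
  submit_signed(ledger, sender_keypair, "REGISTER",
                list(subject_address = subject_keypair$address,
                     public_key = subject_keypair$pubkey_hex,
                     role = role))
}

#' Grant a registered grantee access to the sender's data
#'
#' @param ledger A [Ledger] object.
#' @param owner_keypair Data owner's keypair (must hold role `owner`).
#' @param grantee Grantee address.
#' @return Submission receipt.
#' @export
ct_grant <- function(ledger, owner_keypair, grantee) {
  submit_signed(ledger, owner_keypair, "GRANT", list(grantee = grantee))
}

#' Revoke a grantee's access
#'
#' Revoking a never-granted grantee is recorded but reports `result = FALSE`
#' and changes no state.
#'
#' @inheritParams ct_grant
#' @return Submission receipt (`result` is `TRUE` iff a consent was removed).
#' @export
ct_revoke <- function(ledger, owner_keypair, grantee) {
  submit_signed(ledger, owner_keypair, "REVOKE", list(grantee = grantee))
}

#' Consent query
#'
#' `TRUE` iff the requester is the (registered) owner themselves or holds the
#' owner's consent; unregistered requesters are always denied.
#'
#' @param ledger A [Ledger] object.
#' @param requester,owner Addresses.
#' @return Logical scalar.
#' @export
has_access <- function(ledger, requester, owner) {
  state_has_access(ledger$state, requester, owner)
}

#' Write a clinical record blob for an owner
#'
#' Accepted only from a registered `producer` holding the owner's consent
#' (or writing for themselves); the blob goes to the off-chain store and only
#' its content hash is appended to the owner's on-chain record list.
#'
#' @param ledger A [Ledger] object.
#' @param producer_keypair Producer's keypair.
#' @param owner Data owner's address.
#' @param blob Raw record bytes.
#' @return Submission receipt.
#' @export
ct_write_record <- function(ledger, producer_keypair, owner, blob) {
  submit_signed(ledger, producer_keypair, "DATA_WRITE",
                list(owner = owner, record_hash = sha256_hex(blob)),
                blob = blob)
}

#' Submit a model update for the current round
#'
#' The contract accepts the update only if the sender is a registered FL
#' client, the signature and nonce are valid, the blob deserializes to the
#' expected gradient-boosted-tree format, and its accuracy on the public
#' validation split reaches the configured floor. Any failure reverts fully.
#'
#' @param ledger A [Ledger] object.
#' @param client_keypair FL client's keypair.
#' @param round Round number (must equal the current round).
#' @param blob Serialized model from [serialize_model()].
#' @param n_local Client training-set size (>= 1).
#' @param reported_metrics Named list of the client's self-reported metrics.
#' @return Submission receipt.
#' @export
ct_submit_model <- function(ledger, client_keypair, round, blob, n_local,
                            reported_metrics = NULL) {
  submit_signed(ledger, client_keypair, "MODEL_SUBMIT",
                list(round = as.integer(round),
                     model_hash = sha256_hex(blob),
                     n_local = as.integer(n_local),
                     reported_metrics = reported_metrics),
                blob = blob)
}

#' Record the aggregation of a round
#'
#' Appends an AGGREGATE transaction carrying the global model hash and the
#' contributor list, and advances the round counter. Rejected when the round
#' has no accepted updates or was already aggregated.
#'
#' @param ledger A [Ledger] object.
#' @param admin_keypair Sequencer/admin keypair.
#' @param round Round being closed.
#' @param blob Serialized global model.
#' @return Submission receipt.
#' @export
ct_record_aggregation <- function(ledger, admin_keypair, round, blob) {
  updates <- round_updates(ledger, round)
  submit_signed(ledger, admin_keypair, "AGGREGATE",
                list(round = as.integer(round),
                     global_model_hash = sha256_hex(blob),
                     contributors = lapply(updates, function(u) u$client)),
                blob = blob)
}

#' Distribute per-contribution rewards for an aggregated round
#'
#' Each accepted contributor's balance grows by `amount_each`; total minted
#' equals `amount_each` times the number of contributors.
#'
#' @param ledger A [Ledger] object.
#' @param admin_keypair Sequencer/admin keypair.
#' @param round Aggregated round.
#' @param amount_each Reward units per contribution.
#' @return Submission receipt.
#' @export
ct_distribute_rewards <- function(ledger, admin_keypair, round, amount_each) {
  submit_signed(ledger, admin_keypair, "REWARD",
                list(round = as.integer(round),
                     amount_each = amount_each))
}

#' Accepted model updates of a round
#'
#' @param ledger A [Ledger] object.
#' @param round Round number.
#' @return List of update refs (`client`, `model_hash`, `n_local`,
#'   `reported_metrics`).
#' @export
round_updates <- function(ledger, round) {
  ledger$state$round_state$accepted_updates[[as.character(round)]] %||% list()
}

#' Reward balance of an address
#'
#' @param ledger A [Ledger] object.
#' @param address Participant address.
#' @return Numeric balance (0 for unknown addresses).
#' @export
balance_of <- function(ledger, address) {
  ledger$state$balances[[address]] %||% 0
}
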