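# Contract state machines: registration, consent, record writes, model
# submission, aggregation bookkeeping and incentives.

test_that("registration respects roles and uniqueness", {
  admin <- keygen(1); nora <- keygen(2); alex <- keygen(3); carol <- keygen(4)
  led <- Ledger$new(admin)

  expect_true(ct_register(led, admin, nora, "owner")$accepted)
  expect_equal(led$state$registry[[nora$address]]$role, "owner")

  # a data owner may register a practitioner (producer) for their own data
  expect_true(ct_register(led, nora, alex, "producer")$accepted)

  expect_equal(ct_register(led, admin, nora, "owner")$reason,
               "already_registered")
  # an owner cannot hand out fl_client or admin roles
  expect_equal(ct_register(led, nora, carol, "admin")$reason, "unauthorized")
  expect_equal(ct_register(led, admin, carol, "superuser")$reason,
               "invalid_role")
})

test_that("grant, revoke and has_access follow the consent story", {
  admin <- keygen(1); nora <- keygen(2); alex <- keygen(3); mallory <- keygen(66)
  led <- Ledger$new(admin)
  ct_register(led, admin, nora, "owner")
  ct_register(led, nora, alex, "producer")

  expect_false(has_access(led, alex$address, nora$address))
  expect_true(ct_grant(led, nora, alex$address)$accepted)
  expect_true(has_access(led, alex$address, nora$address))

  # revoke, then re-grant
  expect_true(ct_revoke(led, nora, alex$address)$result)
  expect_false(has_access(led, alex$address, nora$address))
  expect_true(ct_grant(led, nora, alex$address)$accepted)
  expect_true(has_access(led, alex$address, nora$address))

  # revoke of a never-granted grantee: recorded, result FALSE, no change
  before <- led$state$consents
  rec <- ct_revoke(led, nora, admin$address)
  expect_true(rec$accepted)
  expect_false(rec$result)
  expect_identical(led$state$consents, before)

  expect_equal(ct_grant(led, nora, mallory$address)$reason, "unknown_grantee")
  expect_equal(ct_grant(led, alex, nora$address)$reason, "unauthorized")
  # unregistered requester always denied, owner self-access always granted
  expect_false(has_access(led, mallory$address, nora$address))
  expect_true(has_access(led, nora$address, nora$address))
})

test_that("random consent histories agree with the brute-force reference map", {
  admin <- keygen(1)
  led <- Ledger$new(admin)
  keys <- c(list(admin), lapply(2:7, keygen))
  addr <- vapply(keys, function(k) k$address, character(1))
  ref <- ref_new(admin$address)

  withr::with_seed(202, {
    for (step in 1:200) {
      kind <- sample(c("register", "grant", "revoke"), 1)
      s <- sample(7, 1); o <- sample(7, 1)
      op <- switch(kind,
        register = list(kind = "register", sender = addr[s],
                        subject = addr[o],
                        role = sample(c("owner", "producer", "consumer"), 1)),
        grant = list(kind = "grant", sender = addr[s], grantee = addr[o]),
        revoke = list(kind = "revoke", sender = addr[s], grantee = addr[o]))
      rec <- switch(kind,
        register = ct_register(led, keys[[s]], keys[[o]], op$role),
        grant = ct_grant(led, keys[[s]], addr[o]),
        revoke = ct_revoke(led, keys[[s]], addr[o]))
      step_ref <- ref_apply(ref, op)
      ref <- step_ref$ref
      if (kind == "register") {
        expect_equal(rec$accepted, step_ref$result)
      } else if (kind == "revoke" && rec$accepted) {
        expect_equal(rec$result, step_ref$result)
      }
      # full query equivalence after every step
      for (a in 1:7) for (b in 1:7) {
        expect_equal(has_access(led, addr[a], addr[b]),
                     ref_has_access(ref, addr[a], addr[b]))
      }
    }
  })
  expect_true(led$verify_chain() || length(led$pending) > 0)
})

test_that("record writes demand producer role plus consent, and go off-chain", {
  admin <- keygen(1); nora <- keygen(2); alex <- keygen(3); carol <- keygen(4)
  led <- Ledger$new(admin)
  ct_register(led, admin, nora, "owner")
  ct_register(led, nora, alex, "producer")
  ct_register(led, nora, carol, "consumer")
  blob <- charToRaw("medication record v1")

  # no consent yet
  expect_equal(ct_write_record(led, alex, nora$address, blob)$reason,
               "unauthorized")
  ct_grant(led, nora, alex$address)
  expect_true(ct_write_record(led, alex, nora$address, blob)$accepted)
  expect_equal(led$state$records[[nora$address]], sha256_hex(blob))
  expect_identical(led$get_offchain(sha256_hex(blob)), blob)

  # consumer role cannot write even with consent
  ct_grant(led, nora, carol$address)
  expect_equal(ct_write_record(led, carol, nora$address, blob)$reason,
               "forbidden_role")
  # unregistered actor
  expect_equal(ct_write_record(led, keygen(66), nora$address, blob)$reason,
               "unauthorized")
  expect_length(led$state$records[[nora$address]], 1L)
})

test_that("model submission is validated for role, round, format and floor", {
  ctx <- make_fl_ledger(n_clients = 2, floor = 0.5)
  led <- ctx$ledger

  # unregistered client
  expect_equal(ct_submit_model(led, keygen(99), 1, ctx$blob, 100)$reason,
               "unauthorized_client")
  # garbage blob
  garbage <- as.raw(rep(7, 500))
  expect_equal(ct_submit_model(led, ctx$clients[[1]], 1, garbage, 100)$reason,
               "format_invalid")
  # wrong round
  expect_equal(ct_submit_model(led, ctx$clients[[1]], 5, ctx$blob, 100)$reason,
               "wrong_round")
  # happy path
  expect_true(ct_submit_model(led, ctx$clients[[1]], 1, ctx$blob, 100)$accepted)
  # one update per client per round
  expect_equal(ct_submit_model(led, ctx$clients[[1]], 1, ctx$blob, 100)$reason,
               "duplicate_update")
  # below the performance floor: a constant-positive model on a balanced-ish
  # validation split scores near the prevalence of ones
  hp <- tiny_hp()
  val <- ctx$validation
  const <- fedchain:::train_gbt(val$x, rep(1L, nrow(val$x)), hp, hp$n_trees)
  acc_const <- evaluate_model(const, val)$accuracy
  strict <- Ledger$new(ctx$admin,
                       ledger_config(performance_floor = min(0.99, acc_const + 0.2),
                                     validation_matrix = val))
  ct_register(strict, ctx$admin, ctx$clients[[2]], "fl_client")
  expect_equal(ct_submit_model(strict, ctx$clients[[2]], 1,
                               serialize_model(const), 100)$reason,
               "performance_below_floor")
  expect_equal(ct_submit_model(led, ctx$clients[[2]], 1, ctx$blob, 0)$reason,
               "format_invalid")
})

test_that("aggregation advances rounds and is counted exactly by the audit trail", {
  ctx <- make_fl_ledger(n_clients = 3)
  led <- ctx$ledger

  # empty round cannot aggregate
  expect_equal(ct_record_aggregation(led, ctx$admin, 1, ctx$blob)$reason,
               "empty_round")

  n_rounds <- 3L
  for (r in seq_len(n_rounds)) {
    for (ck in ctx$clients) {
      expect_true(ct_submit_model(led, ck, r, ctx$blob, 50)$accepted)
    }
    rec <- ct_record_aggregation(led, ctx$admin, r, ctx$blob)
    expect_true(rec$accepted)
    expect_equal(ct_record_aggregation(led, ctx$admin, r, ctx$blob)$reason,
                 "already_aggregated")
    led$seal_block()
  }
  agg_txs <- led$audit_trail(tx_type = "AGGREGATE")
  expect_length(agg_txs, n_rounds)
  expect_length(agg_txs[[1]]$payload$contributors, 3L)
  # oracle: brute-force scan over all sealed blocks
  scan <- Filter(function(tx) tx$tx_type == "AGGREGATE",
                 do.call(c, lapply(led$chain, function(b) b$tx_list)))
  expect_length(scan, n_rounds)
  expect_equal(led$state$round_state$current_round, n_rounds + 1L)
})

test_that("rewards are conserved and distributed per contribution", {
  ctx <- make_fl_ledger(n_clients = 3)
  led <- ctx$ledger
  bystander <- keygen(77)

  expect_equal(ct_distribute_rewards(led, ctx$admin, 1, 10)$reason,
               "not_aggregated")
  for (r in 1:3) {
    for (ck in ctx$clients) ct_submit_model(led, ck, r, ctx$blob, 50)
    ct_record_aggregation(led, ctx$admin, r, ctx$blob)
    expect_true(ct_distribute_rewards(led, ctx$admin, r, 10)$accepted)
    expect_equal(ct_distribute_rewards(led, ctx$admin, r, 10)$reason,
                 "already_rewarded")
  }
  # equal contributions over 3 rounds -> equal balances (arithmetic replay)
  bals <- vapply(ctx$clients, function(k) balance_of(led, k$address),
                 numeric(1))
  expect_equal(bals, rep(30, 3))
  expect_equal(balance_of(led, bystander$address), 0)
  # conservation: sum of balances equals total minted over REWARD txs
  minted <- sum(vapply(led$audit_trail(tx_type = "REWARD"), function(tx) {
    tx$payload$amount_each *
      length(round_updates(led, tx$payload$round))
  }, numeric(1)))
  expect_equal(sum(unlist(led$state$balances)), minted)
})
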