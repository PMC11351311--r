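# Model blobs, local training, distillation aggregation, metrics, tuning,
# and the orchestrated loop.

test_that("model blobs round-trip exactly and reject garbage", {
  fm <- tiny_fm(n = 100, seed = 2)
  m <- init_global(fm, tiny_hp())
  blob <- serialize_model(m)
  back <- deserialize_model(blob)
  expect_identical(fedchain:::predict_prob(back, fm),
                   fedchain:::predict_prob(m, fm))
  expect_equal(back$hp$n_trees, tiny_hp()$n_trees)

  # deterministic: same subset + seed -> byte-identical blob
  blob2 <- serialize_model(init_global(fm, tiny_hp()))
  expect_identical(blob, blob2)

  expect_error(deserialize_model(as.raw(1:100)), "not a model blob")
  expect_error(deserialize_model(serialize(list(a = 1), NULL)), "format")

  # the encryption hook round-trips when both sides share the cipher
  xor_cipher <- model_cipher(encrypt = function(b) xor(b, as.raw(0x5a)),
                             decrypt = function(b) xor(b, as.raw(0x5a)))
  ct <- serialize_model(m, cipher = xor_cipher)
  expect_false(identical(ct, blob))
  expect_identical(fedchain:::predict_prob(deserialize_model(ct, xor_cipher), fm),
                   fedchain:::predict_prob(m, fm))
  expect_error(deserialize_model(ct), "not a model blob")  # wrong/no cipher
})

test_that("global init fits a separable toy set perfectly and needs both classes", {
  x <- cbind(a = c(rep(0, 20), rep(1, 20)), b = 0)
  fm <- feature_matrix(x, c(rep(0L, 20), rep(1L, 20)))
  m <- init_global(fm, tiny_hp())
  expect_equal(evaluate_model(m, fm)$accuracy, 1)

  single <- feature_matrix(x, rep(0L, 40))
  expect_error(init_global(single, tiny_hp()), "both classes")
})

test_that("local fine-tuning appends trees and never hurts on redundant data", {
  init <- tiny_fm(n = 200, seed = 3)
  test <- tiny_fm(n = 400, seed = 4)
  hp <- tiny_hp()
  global <- init_global(init, hp)
  n0 <- xgboost::xgb.get.num.boosted.rounds(global$booster)

  local <- local_train(global, init, hp)  # shard identical to init subset
  expect_equal(xgboost::xgb.get.num.boosted.rounds(local$booster),
               n0 + hp$local_trees)
  g <- evaluate_model(global, test); l <- evaluate_model(local, test)
  expect_gte(l$accuracy, g$accuracy - 0.02)
  expect_gte(l$f1, g$f1 - 0.02)

  single <- feature_matrix(init$x, rep(1L, nrow(init$x)))
  expect_message(out <- local_train(global, single, hp), "skipping")
  expect_null(out)
  bad_hp <- hp; bad_hp$local_trees <- 0L
  expect_error(local_train(global, init, bad_hp), "local_trees")
})

test_that("a client holding signal absent from the init subset lifts recall", {
  # outcome depends on features a and b; the init subset only sees rows with
  # small b, so the global model can only learn the a-channel
  gen <- function(n, seed, b_max = 1) {
    withr::with_seed(seed, {
      x <- cbind(a = stats::runif(n), b = stats::runif(n, 0, b_max))
      y <- as.integer(x[, "a"] > 0.85 | x[, "b"] > 0.85)
    })
    feature_matrix(x, y)
  }
  init <- gen(300, 1, b_max = 0.5)
  shard <- gen(600, 2)
  test <- gen(1000, 3)
  hp <- fl_hyperparams(n_trees = 30, max_depth = 3, local_trees = 30, seed = 1)
  global <- init_global(init, hp)
  local <- local_train(global, shard, hp)
  expect_gt(evaluate_model(local, test)$recall,
            evaluate_model(global, test)$recall)
})

test_that("distillation aggregation mimics clients and collapses duplicates", {
  distill <- tiny_fm(n = 300, seed = 5)
  hp <- tiny_hp()
  client <- init_global(tiny_fm(n = 200, seed = 6), hp)

  # single client: global agrees with the client's hard labels on >= 95%
  global <- aggregate_models(list(client), 1, distill, hp)
  client_labels <- as.integer(fedchain:::predict_prob(client, distill) >= 0.5)
  global_labels <- as.integer(fedchain:::predict_prob(global, distill) >= 0.5)
  expect_gte(mean(client_labels == global_labels), 0.95)

  # K identical clients with any weights equal the single-client result
  global3 <- aggregate_models(list(client, client, client), c(0.2, 0.5, 0.3),
                              distill, hp)
  expect_identical(serialize_model(global3), serialize_model(global))

  expect_error(aggregate_models(list(), numeric(0), distill, hp), "at least one")
  expect_error(aggregate_models(list(client), -1, distill, hp), "non-negative")
})

test_that("a 0.7/0.3 all-positive/all-negative vote forces an all-positive global", {
  distill <- tiny_fm(n = 300, seed = 7)
  hp <- tiny_hp()
  all_pos <- fedchain:::train_gbt(distill$x, rep(1L, 300), hp, hp$n_trees)
  all_neg <- fedchain:::train_gbt(distill$x, rep(0L, 300), hp, hp$n_trees)
  p_pos <- fedchain:::predict_prob(all_pos, distill)
  p_neg <- fedchain:::predict_prob(all_neg, distill)
  pbar <- 0.7 * p_pos + 0.3 * p_neg
  expect_true(all(pbar >= 0.5))  # the forced-vote premise

  for (mode in c("hard", "soft")) {
    global <- aggregate_models(list(all_pos, all_neg), c(0.7, 0.3), distill,
                               hp, mode = mode)
    expect_true(all(fedchain:::predict_prob(global, distill) >= 0.5))
  }
})

test_that("metrics match hand-computed confusion arithmetic and zero rules", {
  # TP=2 FP=1 FN=1 TN=6
  y    <- c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  pred <- c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  m <- fedchain:::confusion_metrics(y, pred)
  expect_equal(m$accuracy, (2 + 6) / 10)
  expect_equal(m$precision, 2 / (2 + 1))
  expect_equal(m$recall, 2 / (2 + 1))
  expect_equal(m$f1, 2 * (2 / 3) * (2 / 3) / (2 / 3 + 2 / 3))

  all_neg <- fedchain:::confusion_metrics(y, rep(0L, 10))
  expect_equal(all_neg$recall, 0)
  expect_equal(all_neg$f1, 0)
  expect_equal(all_neg$precision, 0)

  perfect <- fedchain:::confusion_metrics(y, y)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
})

test_that("random-search tuning is seeded and finds the exhaustive-grid optimum", {
  train <- tiny_fm(n = 150, seed = 8)
  val <- tiny_fm(n = 150, seed = 9)

  one <- tune_hyperparams(train, val, budget = 1, seed = 4)
  expect_true(is.list(one) && !is.null(one$n_trees))
  expect_identical(tune_hyperparams(train, val, budget = 5, seed = 4),
                   tune_hyperparams(train, val, budget = 5, seed = 4))

  # exhaustive oracle over the declared grid
  grid <- expand.grid(n_trees = c(25L, 50L, 100L),
                      max_depth = c(2L, 3L, 4L, 6L),
                      learning_rate = c(0.05, 0.1, 0.2, 0.3))
  oracle_best <- max(vapply(seq_len(nrow(grid)), function(r) {
    hp <- fl_hyperparams(grid$n_trees[r], grid$max_depth[r],
                         grid$learning_rate[r])
    evaluate_model(fedchain:::train_gbt(train$x, train$y, hp, hp$n_trees), val)$f1
  }, numeric(1)))
  full <- tune_hyperparams(train, val, budget = nrow(grid), seed = 1)
  expect_equal(attr(full, "f1"), oracle_best)
  expect_error(tune_hyperparams(train, val, budget = 0), "budget")
})

test_that("a zero-round run returns the init model and an empty history", {
  coh <- generate_cohort(generator_config(n = 1500, seed = 31))
  cfg <- fl_config(n_clients = 3, n_rounds = 0, master_seed = 7)
  run <- run_rounds(cfg, coh)
  expect_equal(nrow(run$history), 0L)
  expect_equal(nrow(run$global_history), 0L)
  expect_length(run$ledger$audit_trail(tx_type = "AGGREGATE"), 0L)

  dat <- fedchain:::prepare_fl_data(cfg, coh)
  init <- init_global(dat$init, cfg$hp)
  expect_identical(fedchain:::predict_prob(run$final_model, dat$test),
                   fedchain:::predict_prob(init, dat$test))
})

test_that("the orchestrated loop records every exchange and respects privacy", {
  coh <- generate_cohort(generator_config(n = 2500, seed = 32))
  cfg <- fl_config(n_clients = 3, n_rounds = 2, master_seed = 8,
                   hp = tiny_hp())
  run <- run_rounds(cfg, coh)

  expect_equal(nrow(run$history), 2L * 3L)           # R x K client entries
  expect_length(run$ledger$audit_trail(tx_type = "AGGREGATE"), 2L)
  expect_length(run$ledger$audit_trail(tx_type = "MODEL_SUBMIT"), 6L)
  expect_true(run$ledger$verify_chain())
  expect_true(all(unlist(run$history[, c("accuracy", "precision",
                                         "recall", "f1")]) >= 0))
  expect_true(all(unlist(run$history[, c("accuracy", "precision",
                                         "recall", "f1")]) <= 1))

  # privacy boundary: shard rows were only ever read by local_train
  touched <- unique(unlist(run$shard_access))
  expect_identical(touched, "local_train")
  expect_gt(length(unlist(run$shard_access)), 0L)

  # every accepted model hash resolves in the off-chain store
  for (tx in run$ledger$audit_trail(tx_type = "MODEL_SUBMIT")) {
    expect_true(is.raw(run$ledger$get_offchain(tx$payload$model_hash)))
  }

  # rewards: 3 clients x 2 rounds x default 10 units
  bals <- vapply(run$clients, function(a) balance_of(run$ledger, a), numeric(1))
  expect_equal(unname(bals), rep(20, 3))
})

test_that("identical master seeds reproduce the run; pooled comparator is close", {
  coh <- generate_cohort(generator_config(n = 2500, seed = 33))
  cfg <- fl_config(n_clients = 3, n_rounds = 2, master_seed = 9,
                   hp = tiny_hp())
  r1 <- run_rounds(cfg, coh)
  r2 <- run_rounds(cfg, coh)
  expect_identical(r1$final_blob, r2$final_blob)
  expect_equal(r1$global_history, r2$global_history)
  expect_identical(r1$ledger$export_chain(), r2$ledger$export_chain())

  pooled <- pooled_comparator(cfg, coh)
  expect_lt(abs(tail(r1$global_history$accuracy, 1) - pooled$accuracy), 0.15)
})
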