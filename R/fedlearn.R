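# Federated training of gradient-boosted tree classifiers. Trees have no
# averageable parameters, so aggregation is knowledge distillation: the
# weighted soft vote of the client models over the public init subset is
# compiled into labels and a fresh global ensemble is retrained on them.
# Every model exchange flows through the ledger/contracts layer.

#' Default gradient-boosted-tree hyperparameters
#'
#' @param n_trees Boosting rounds for global (re)training.
#' @param max_depth Tree depth.
#' @param learning_rate Shrinkage (eta).
#' @param local_trees Trees appended per client per round during local
#'   fine-tuning (continued boosting).
#' @param seed xgboost RNG seed.
#' @return Named list of hyperparameters.
#' @export
fl_hyperparams <- function(n_trees = 60L, max_depth = 3L,
                           learning_rate = 0.3, local_trees = 20L,
                           seed = 1L) {
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       learning_rate = learning_rate, local_trees = as.integer(local_trees),
       seed = as.integer(seed))
}

MODEL_FORMAT_TAG <- "fedchain-gbt-1"

#' Encryption hook for model blobs
#'
#' Interface point for encrypting model updates at rest and in transit. The
#' simulation ships it as a pass-through (identity in both directions), since
#' update confidentiality here rests on signing plus off-chain storage; a
#' deployment wanting ciphertext blobs supplies its own pair and shares it
#' between clients and the validating contract.
#'
#' @param encrypt,decrypt Functions raw -> raw; must be mutual inverses.
#' @return A `model_cipher`.
#' @export
model_cipher <- function(encrypt = identity, decrypt = identity) {
  stopifnot(is.function(encrypt), is.function(decrypt))
  structure(list(encrypt = encrypt, decrypt = decrypt),
            class = "model_cipher")
}

train_gbt <- function(x, y, hp, nrounds, base_model = NULL,
                      objective = "binary:logistic") {
  d <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  # fixed base_score: keeps training defined for single-class label vectors
  # (constant-prediction models) and byte-reproducible across runs
  params <- list(objective = objective, max_depth = hp$max_depth,
                 eta = hp$learning_rate, nthread = 1, seed = hp$seed,
                 base_score = 0.5)
  booster <- xgboost::xgb.train(params = params, data = d,
                                nrounds = nrounds, verbose = 0,
                                xgb_model = base_model)
  structure(list(booster = booster, hp = hp, objective = objective),
            class = "fl_model")
}

#' @export
print.fl_model <- function(x, ...) {
  cat(sprintf("<fl_model> %s, %d trees, depth %d, eta %g\n", x$objective,
              xgboost::xgb.get.num.boosted.rounds(x$booster),
              x$hp$max_depth, x$hp$learning_rate))
  invisible(x)
}

predict_prob <- function(model, fm) {
  stats::predict(model$booster, xgboost::xgb.DMatrix(fm$x, nthread = 1))
}

#' Serialize / deserialize a model blob
#'
#' A blob carries a format version tag, the training hyperparameters and the
#' raw xgboost booster bytes. Deserializing the serialization of a model
#' predicts identically to the original; anything that is not a valid blob
#' (wrong tag, truncated bytes, random garbage) raises an error, which the
#' contract layer converts into a `format_invalid` rejection.
#'
#' @param model An `fl_model`.
#' @param blob Raw vector produced by `serialize_model`.
#' @param cipher A [model_cipher()]; the default passes bytes through
#'   unchanged.
#' @return `serialize_model`: a raw vector; `deserialize_model`: an
#'   `fl_model`.
#' @export
serialize_model <- function(model, cipher = model_cipher()) {
  stopifnot(inherits(model, "fl_model"))
  cipher$encrypt(serialize(list(format = MODEL_FORMAT_TAG,
                                hp = model$hp,
                                objective = model$objective,
                                booster = xgboost::xgb.save.raw(model$booster)),
                           connection = NULL, version = 3L))
}

#' @rdname serialize_model
#' @export
deserialize_model <- function(blob, cipher = model_cipher()) {
  stopifnot(is.raw(blob))
  blob <- cipher$decrypt(blob)
  obj <- tryCatch(unserialize(blob),
                  error = function(e) stop("not a model blob", call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT_TAG) ||
      !is.raw(obj$booster) || !is.list(obj$hp)) {
    stop("not a model blob (bad format tag)", call. = FALSE)
  }
  booster <- tryCatch(xgboost::xgb.load.raw(obj$booster),
                      error = function(e) stop("corrupt booster bytes",
                                               call. = FALSE))
  structure(list(booster = booster, hp = obj$hp,
                 objective = obj$objective %||% "binary:logistic"),
            class = "fl_model")
}

# ---- per-shard access logging (privacy boundary instrumentation) ----------

fm_with_access_log <- function(fm) {
  attr(fm, "access_log") <- new.env(parent = emptyenv())
  attr(fm, "access_log")$entries <- character(0)
  fm
}

fm_log_access <- function(fm, accessor) {
  lg <- attr(fm, "access_log")
  if (!is.null(lg)) lg$entries <- c(lg$entries, accessor)
  invisible(fm)
}

fm_access_entries <- function(fm) {
  lg <- attr(fm, "access_log")
  if (is.null(lg)) character(0) else lg$entries
}

# ---- training operations ---------------------------------------------------

#' Initialize the global model on the public subset
#'
#' @param public_fm The public init [feature_matrix()] (must contain both
#'   classes).
#' @param hp Hyperparameters from [fl_hyperparams()].
#' @return An `fl_model`.
#' @export
init_global <- function(public_fm, hp = fl_hyperparams()) {
  fm_log_access(public_fm, "init_global")
  if (length(unique(public_fm$y)) < 2L) {
    stop("init subset must contain both classes", call. = FALSE)
  }
  train_gbt(public_fm$x, public_fm$y, hp, nrounds = hp$n_trees)
}

#' Fine-tune the global model on a client shard
#'
#' Continued boosting: `hp$local_trees` new trees are appended to the
#' received global ensemble, fit to the shard. Only the resulting model ever
#' leaves the client. A single-class shard makes the client skip the round
#' (returns `NULL` with a message).
#'
#' @param global The current global `fl_model`.
#' @param shard The client's private [feature_matrix()].
#' @param hp Hyperparameters; `local_trees` must be >= 1.
#' @return An `fl_model`, or `NULL` if the client skips.
#' @export
local_train <- function(global, shard, hp = global$hp) {
  stopifnot(inherits(global, "fl_model"))
  if (hp$local_trees < 1L) {
    stop("local_trees must be at least 1", call. = FALSE)
  }
  if (length(unique(shard$y)) < 2L) {
    message("client shard has a single class; skipping this round")
    return(NULL)
  }
  fm_log_access(shard, "local_train")
  train_gbt(shard$x, shard$y, hp, nrounds = hp$local_trees,
            base_model = global$booster)
}

#' Aggregate client models by prediction distillation
#'
#' Computes the weighted mean positive probability `pbar(x)` of the client
#' models over the distillation set, then either retrains a fresh classifier
#' on the hard labels `1{pbar >= 0.5}` (ties to positive; `mode = "hard"`,
#' default) or fits a regressor to `pbar` and thresholds at predict time
#' (`mode = "soft"`).
#'
#' @param models List of client `fl_model`s (length >= 1).
#' @param weights Non-negative weights, one per model (normalized
#'   internally).
#' @param distill_fm The public distillation [feature_matrix()] (the init
#'   subset; client data is never used here).
#' @param hp Hyperparameters for the retrained global.
#' @param mode `"hard"` or `"soft"`.
#' @return The new global `fl_model`.
#' @export
aggregate_models <- function(models, weights, distill_fm,
                             hp = fl_hyperparams(), mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  if (length(models) == 0L) stop("need at least one model", call. = FALSE)
  if (nrow(distill_fm$x) == 0L) stop("empty distillation set", call. = FALSE)
  if (length(weights) != length(models) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  fm_log_access(distill_fm, "aggregate")
  w <- weights / sum(weights)
  pbar <- Reduce(`+`, Map(function(m, wi) wi * predict_prob(m, distill_fm),
                          models, w))
  if (mode == "hard") {
    labels <- as.integer(pbar >= 0.5)
    train_gbt(distill_fm$x, labels, hp, nrounds = hp$n_trees)
  } else {
    train_gbt(distill_fm$x, pbar, hp, nrounds = hp$n_trees,
              objective = "reg:squarederror")
  }
}

#' Classification metrics on a test set
#'
#' Predicts positive iff the model probability is at least 0.5 and computes
#' accuracy, precision, recall and F1. A zero denominator (no predicted
#' positives, no true positives) yields 0 for the affected metric.
#'
#' @param model An `fl_model` or serialized blob.
#' @param test A non-empty [feature_matrix()].
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate_model <- function(model, test) {
  if (is.raw(model)) model <- deserialize_model(model)
  stopifnot(inherits(model, "fl_model"), nrow(test$x) > 0L)
  fm_log_access(test, "evaluate")
  pred <- as.integer(predict_prob(model, test) >= 0.5)
  confusion_metrics(test$y, pred)
}

confusion_metrics <- function(y, pred) {
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  list(accuracy = (tp + tn) / length(y),
       precision = precision,
       recall = recall,
       f1 = safe_div(2 * precision * recall, precision + recall))
}

#' Seeded random-search hyperparameter tuning
#'
#' Samples `budget` settings from a declared grid over `n_trees`,
#' `max_depth` and `learning_rate`, trains each on `train_fm` and returns
#' the setting maximizing F1 on `val_fm` (ties to the first trial found).
#'
#' @param train_fm,val_fm Training and validation [feature_matrix()]s.
#' @param budget Number of trials (>= 1).
#' @param seed Integer seed for the search.
#' @return Hyperparameter list as from [fl_hyperparams()], with attribute
#'   `"f1"` holding the best validation F1.
#' @export
tune_hyperparams <- function(train_fm, val_fm, budget = 10L, seed = 1L) {
  if (budget < 1L) stop("budget must be at least 1", call. = FALSE)
  grid <- expand.grid(n_trees = c(25L, 50L, 100L),
                      max_depth = c(2L, 3L, 4L, 6L),
                      learning_rate = c(0.05, 0.1, 0.2, 0.3))
  rows <- withr::with_seed(seed,
    sample(nrow(grid), min(budget, nrow(grid))))
  best <- NULL; best_f1 <- -1
  for (r in rows) {
    hp <- fl_hyperparams(n_trees = grid$n_trees[r],
                         max_depth = grid$max_depth[r],
                         learning_rate = grid$learning_rate[r])
    m <- train_gbt(train_fm$x, train_fm$y, hp, nrounds = hp$n_trees)
    f1 <- evaluate_model(m, val_fm)$f1
    if (f1 > best_f1) { best <- hp; best_f1 <- f1 }
  }
  attr(best, "f1") <- best_f1
  best
}

# ---- orchestration ---------------------------------------------------------

#' Federated-run configuration
#'
#' @param n_clients Number of participating nodes (default 5).
#' @param n_rounds Training rounds (default 10).
#' @param init_fraction,validation_fraction,test_fraction Proportions of the
#'   cohort reserved for the public init/distillation subset, the public
#'   validation split used by the contract's performance check, and the
#'   shared held-out test set; the remainder is split across clients.
#' @param partition_mode `"iid"` or `"label_skew"`.
#' @param alpha Dirichlet concentration for label skew.
#' @param weight_mode `"by_size"` (client weight proportional to local
#'   training-set size) or `"uniform"`.
#' @param distill_mode `"hard"` or `"soft"` distillation labels.
#' @param undersample_ratio Majority:minority target per client shard.
#' @param performance_floor Contract-level accuracy floor for update
#'   acceptance.
#' @param reward_per_contribution Reward units minted per accepted update.
#' @param hp Hyperparameters from [fl_hyperparams()].
#' @param master_seed Single seed from which all per-stage seeds derive.
#' @param adversary Optional callback `function(ledger, round, admin_key)`
#'   invoked once per round after the honest submissions; used by attack
#'   scenarios to inject adversarial transactions mid-run.
#' @return An `fl_config` list.
#' @export
fl_config <- function(n_clients = 5L, n_rounds = 10L,
                      init_fraction = 0.10, validation_fraction = 0.10,
                      test_fraction = 0.20,
                      partition_mode = "iid", alpha = 0.5,
                      weight_mode = c("by_size", "uniform"),
                      distill_mode = c("hard", "soft"),
                      undersample_ratio = 1,
                      performance_floor = 0.5,
                      reward_per_contribution = 10,
                      hp = fl_hyperparams(),
                      master_seed = 1L,
                      adversary = NULL) {
  stopifnot(n_clients >= 1L, n_rounds >= 0L)
  if (init_fraction + validation_fraction + test_fraction >= 1) {
    stop("init + validation + test fractions must leave room for clients",
         call. = FALSE)
  }
  structure(list(n_clients = as.integer(n_clients),
                 n_rounds = as.integer(n_rounds),
                 init_fraction = init_fraction,
                 validation_fraction = validation_fraction,
                 test_fraction = test_fraction,
                 partition_mode = partition_mode, alpha = alpha,
                 weight_mode = match.arg(weight_mode),
                 distill_mode = match.arg(distill_mode),
                 undersample_ratio = undersample_ratio,
                 performance_floor = performance_floor,
                 reward_per_contribution = reward_per_contribution,
                 hp = hp, master_seed = as.integer(master_seed),
                 adversary = adversary),
            class = "fl_config")
}

# all per-stage seeds derive from the master seed by fixed offsets
derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 7919 + offset) %% 2147483647)
}

# Split + preprocess a raw cohort into the FL data layout. Preprocessing
# statistics are fitted on the public init subset only and applied
# everywhere, so clients never exchange statistics of private rows.
prepare_fl_data <- function(config, cohort) {
  n <- nrow(cohort)
  ord <- withr::with_seed(derive_seed(config$master_seed, 1L), sample(n))
  n_init <- max(2L, round(config$init_fraction * n))
  n_val <- max(2L, round(config$validation_fraction * n))
  n_test <- max(2L, round(config$test_fraction * n))
  if (n_init + n_val + n_test + config$n_clients > n) {
    stop("cohort too small for the configured splits", call. = FALSE)
  }
  idx_init <- ord[seq_len(n_init)]
  idx_val <- ord[n_init + seq_len(n_val)]
  idx_test <- ord[n_init + n_val + seq_len(n_test)]
  idx_rest <- ord[-seq_len(n_init + n_val + n_test)]

  pp_imp <- fit_impute(cohort[idx_init, , drop = FALSE])
  coh <- apply_impute(cohort, pp_imp)
  pp_enc <- fit_encode(coh[idx_init, , drop = FALSE])
  fm_all <- apply_encode(coh, pp_enc, provenance = "cohort")
  pp_sc <- fit_scale(fm_subset(fm_all, idx_init))
  fm_all <- apply_scale(fm_all, pp_sc)

  shards_raw <- partition_shards(fm_subset(fm_all, idx_rest),
                                 config$n_clients,
                                 mode = config$partition_mode,
                                 alpha = config$alpha,
                                 seed = derive_seed(config$master_seed, 2L))
  # cohort rows behind each client's raw chunk (pre-undersampling): this is
  # what a centralized upload would have to move
  shard_rows <- lapply(shards_raw, function(s) idx_rest[attr(s, "indices")])
  shards <- lapply(seq_along(shards_raw), function(i) {
    sh <- undersample(shards_raw[[i]], ratio = config$undersample_ratio,
                      seed = derive_seed(config$master_seed, 300L + i))
    sh$provenance <- sprintf("client%d", i)
    sh
  })
  list(init = fm_subset(fm_all, idx_init),
       validation = fm_subset(fm_all, idx_val),
       test = fm_subset(fm_all, idx_test),
       shards = shards, shard_rows = shard_rows,
       params = list(impute = pp_imp, encode = pp_enc, scale = pp_sc))
}

#' Run the full federated training loop
#'
#' Orchestrates the complete simulation on a raw cohort: split into public
#' init / validation / test subsets and client shards (per-shard
#' undersampling), initialize the global model on the init subset, then per
#' round: broadcast the global model (counted as downlink bytes), fine-tune
#' per client, submit each update through the contract layer (signature,
#' format and performance validation), aggregate the accepted updates by
#' distillation on the init subset, record the aggregation and distribute
#' rewards on the ledger, and evaluate every client model and the new global
#' on the shared test set. One block is sealed per round, so every model
#' exchange is on the chain.
#'
#' @param config An [fl_config()].
#' @param cohort A raw cohort data.frame from [generate_cohort()] (or the
#'   same schema read from CSV).
#' @return An `fl_run`: `history` (per round x client metrics),
#'   `global_history` (per round global metrics and byte counts),
#'   `final_model`, `final_blob`, `ledger`, `clients` (addresses),
#'   `shard_bytes`, `shard_access` (privacy-boundary log), `data` (the
#'   public splits), and `config`.
#' @export
run_rounds <- function(config, cohort) {
  stopifnot(inherits(config, "fl_config"))
  dat <- prepare_fl_data(config, cohort)
  dat$shards <- lapply(dat$shards, fm_with_access_log)
  K <- config$n_clients

  admin <- keygen(derive_seed(config$master_seed, 9000L))
  client_keys <- lapply(seq_len(K), function(i)
    keygen(derive_seed(config$master_seed, 9000L + i)))
  ledger <- Ledger$new(admin, ledger_config(
    performance_floor = config$performance_floor,
    validation_matrix = dat$validation))
  for (ck in client_keys) {
    stopifnot(ct_register(ledger, admin, ck, "fl_client")$accepted)
  }
  ledger$seal_block()

  hp <- config$hp
  global <- init_global(dat$init, hp)
  global_blob <- serialize_model(global)
  ledger$put_offchain(global_blob)

  history <- list()
  global_history <- list()
  for (r in seq_len(config$n_rounds)) {
    bytes_down <- length(global_blob) * K
    bytes_up <- 0
    local_models <- vector("list", K)
    for (k in seq_len(K)) {
      hp_k <- hp; hp_k$seed <- derive_seed(config$master_seed, 100L * r + k)
      local <- local_train(global, dat$shards[[k]], hp_k)
      if (is.null(local)) next
      local_models[[k]] <- local
      blob <- serialize_model(local)
      bytes_up <- bytes_up + length(blob)
      rec <- ct_submit_model(ledger, client_keys[[k]], r, blob,
                             n_local = nrow(dat$shards[[k]]$x),
                             reported_metrics =
                               evaluate_model(local, dat$validation))
      if (!rec$accepted) {
        message(sprintf("round %d: client %d update rejected (%s)",
                        r, k, rec$reason))
      }
    }
    if (!is.null(config$adversary)) config$adversary(ledger, r, admin)
    updates <- round_updates(ledger, r)
    if (length(updates) > 0L) {
      models <- lapply(updates, function(u)
        deserialize_model(ledger$get_offchain(u$model_hash)))
      weights <- if (config$weight_mode == "by_size") {
        vapply(updates, function(u) as.numeric(u$n_local), numeric(1))
      } else rep(1, length(updates))
      hp_g <- hp; hp_g$seed <- derive_seed(config$master_seed, 5000L + r)
      global <- aggregate_models(models, weights, dat$init, hp_g,
                                 mode = config$distill_mode)
      global_blob <- serialize_model(global)
      stopifnot(ct_record_aggregation(ledger, admin, r, global_blob)$accepted)
      stopifnot(ct_distribute_rewards(
        ledger, admin, r, config$reward_per_contribution)$accepted)
    } else {
      message(sprintf("round %d: no accepted updates; keeping prior global", r))
    }
    for (k in seq_len(K)) {
      if (is.null(local_models[[k]])) next
      m <- evaluate_model(local_models[[k]], dat$test)
      history[[length(history) + 1L]] <-
        data.frame(round = r, client = k,
                   address = client_keys[[k]]$address,
                   accuracy = m$accuracy, precision = m$precision,
                   recall = m$recall, f1 = m$f1)
    }
    g <- evaluate_model(global, dat$test)
    global_history[[length(global_history) + 1L]] <-
      data.frame(round = r, accuracy = g$accuracy, precision = g$precision,
                 recall = g$recall, f1 = g$f1,
                 bytes_up = bytes_up, bytes_down = bytes_down)
    ledger$seal_block()
  }

  structure(list(
    history = do.call(rbind, history) %||%
      data.frame(round = integer(0), client = integer(0),
                 address = character(0), accuracy = numeric(0),
                 precision = numeric(0), recall = numeric(0),
                 f1 = numeric(0)),
    global_history = do.call(rbind, global_history) %||%
      data.frame(round = integer(0), accuracy = numeric(0),
                 precision = numeric(0), recall = numeric(0),
                 f1 = numeric(0), bytes_up = numeric(0),
                 bytes_down = numeric(0)),
    final_model = global,
    final_blob = global_blob,
    ledger = ledger,
    clients = vapply(client_keys, function(k) k$address, character(1)),
    client_keys = client_keys,
    admin_key = admin,
    shard_bytes = vapply(dat$shard_rows, function(ix)
      cohort_serialized_bytes(cohort[ix, , drop = FALSE]), numeric(1)),
    shard_access = lapply(dat$shards, fm_access_entries),
    data = dat[c("init", "validation", "test")],
    config = config
  ), class = "fl_run")
}

#' @export
print.fl_run <- function(x, ...) {
  gh <- x$global_history
  cat(sprintf("<fl_run> %d clients, %d rounds", x$config$n_clients,
              x$config$n_rounds))
  if (nrow(gh) > 0) {
    cat(sprintf("; final global acc %.3f f1 %.3f",
                gh$accuracy[nrow(gh)], gh$f1[nrow(gh)]))
  }
  cat("\n")
  invisible(x)
}

#' Centralized (pooled-data) comparator
#'
#' Trains one model on the union of the client shards — the non-private
#' baseline the federated run is compared against — using the same splits,
#' preprocessing, undersampling and hyperparameters as [run_rounds()] with
#' the same config, and evaluates it on the shared test set.
#'
#' @param config An [fl_config()].
#' @param cohort The same raw cohort passed to [run_rounds()].
#' @return Metrics list from [evaluate_model()] with attribute `"model"`.
#' @export
pooled_comparator <- function(config, cohort) {
  dat <- prepare_fl_data(config, cohort)
  x <- do.call(rbind, lapply(dat$shards, function(s) s$x))
  y <- do.call(c, lapply(dat$shards, function(s) s$y))
  pooled <- feature_matrix(x, y, "pooled")
  model <- train_gbt(pooled$x, pooled$y, config$hp,
                     nrounds = config$hp$n_trees)
  out <- evaluate_model(model, dat$test)
  attr(out, "model") <- model
  out
}
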