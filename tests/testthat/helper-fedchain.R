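# Shared fixtures, all built in code.

# Small learnable binary problem: label driven by feature `a` with noise.
tiny_fm <- function(n = 80, seed = 1, prevalence_shift = 0) {
  withr::with_seed(seed, {
    x <- cbind(a = stats::runif(n), b = stats::runif(n))
    y <- as.integer(stats::runif(n) <
                      stats::plogis(6 * (x[, "a"] - 0.5) + prevalence_shift))
  })
  feature_matrix(x, y, "tiny")
}

tiny_hp <- function(seed = 1) {
  fl_hyperparams(n_trees = 15L, max_depth = 2L, learning_rate = 0.3,
                 local_trees = 5L, seed = seed)
}

# Ledger with admin + registered FL clients and a validation split, plus a
# valid model blob trained on a matching problem.
make_fl_ledger <- function(n_clients = 2, floor = 0.5, seed = 1) {
  val <- tiny_fm(n = 100, seed = seed + 50)
  admin <- keygen(seed)
  clients <- lapply(seq_len(n_clients), function(i) keygen(seed + i))
  ledger <- Ledger$new(admin, ledger_config(performance_floor = floor,
                                            validation_matrix = val))
  for (ck in clients) stopifnot(ct_register(ledger, admin, ck, "fl_client")$accepted)
  train <- tiny_fm(n = 120, seed = seed + 60)
  model <- init_global(train, tiny_hp(seed))
  list(ledger = ledger, admin = admin, clients = clients,
       validation = val, model = model, blob = serialize_model(model))
}

# Independent reference implementation of the access-control state machine:
# plain maps, no ledger, no signatures. Used as the brute-force oracle.
ref_new <- function(admin) {
  list(registry = stats::setNames(list("admin"), admin),
       consents = list())
}

ref_apply <- function(ref, op) {
  res <- FALSE
  switch(op$kind,
    register = {
      sender_role <- ref$registry[[op$sender]]
      authorized <- identical(sender_role, "admin") ||
        (identical(sender_role, "owner") && op$role %in% c("producer", "consumer"))
      if (authorized && is.null(ref$registry[[op$subject]]) &&
          op$role %in% c("owner", "producer", "consumer", "fl_client", "admin")) {
        ref$registry[[op$subject]] <- op$role
        res <- TRUE
      }
    },
    grant = {
      if (identical(ref$registry[[op$sender]], "owner") &&
          !is.null(ref$registry[[op$grantee]])) {
        ref$consents[[op$sender]] <- union(ref$consents[[op$sender]], op$grantee)
        res <- TRUE
      }
    },
    revoke = {
      if (identical(ref$registry[[op$sender]], "owner")) {
        res <- op$grantee %in% (ref$consents[[op$sender]] %||% character(0))
        ref$consents[[op$sender]] <- setdiff(ref$consents[[op$sender]], op$grantee)
      }
    }
  )
  list(ref = ref, result = res)
}

ref_has_access <- function(ref, requester, owner) {
  !is.null(ref$registry[[requester]]) &&
    (identical(requester, owner) ||
       requester %in% (ref$consents[[owner]] %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
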