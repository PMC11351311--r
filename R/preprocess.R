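# Preprocessing pipeline: fit/apply imputation, categorical encoding, min-max
# scaling, class rebalancing by undersampling, and partitioning into client
# shards. All fit_* functions learn statistics that apply_* re-uses, so the
# orchestrator can fit on its public init subset and distribute the fitted
# parameters — clients never exchange statistics of their private rows.

#' Feature matrix container
#'
#' Numeric design matrix plus binary label vector, the unit of exchange for
#' model training and evaluation. Invariants: no missing entries, all finite,
#' row count equals label length.
#'
#' @param x Numeric matrix (rows = subjects) with column names.
#' @param y Binary 0/1 integer label vector.
#' @param provenance Free-text tag recording which cohort/params produced it.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(x, y, provenance = "") {
  stopifnot(is.matrix(x), is.numeric(x))
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("row count must equal label length", call. = FALSE)
  if (length(y) && !all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(x) && !all(is.finite(x))) {
    stop("feature matrix must be complete and finite", call. = FALSE)
  }
  structure(list(x = x, y = y, provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d, prevalence %.3f%s\n",
              nrow(x$x), ncol(x$x), if (length(x$y)) mean(x$y) else NA,
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

fm_subset <- function(fm, idx) {
  feature_matrix(fm$x[idx, , drop = FALSE], fm$y[idx], fm$provenance)
}

feature_cols <- function(cohort) setdiff(names(cohort), c("subject_id", "diabetes"))

is_categorical <- function(col) is.character(col) || is.factor(col)

mode_of <- function(x) {
  x <- x[!is.na(x)]
  tab <- sort(table(x), decreasing = TRUE)
  # ties break towards the lexicographically first level for determinism
  names(tab)[which(tab == tab[1])][order(names(tab)[tab == tab[1]])][1]
}

#' Fit / apply imputation
#'
#' `fit_impute` learns, per feature column, either a drop decision (missing
#' fraction above `drop_threshold`) or a fill value (median for numeric, mode
#' for categorical, ties to the lexicographically first level).
#' `apply_impute` drops and fills accordingly; fitting and application are
#' separable so clients can apply centrally fitted statistics.
#'
#' @param cohort A cohort data.frame (label column `diabetes` untouched).
#' @param policy List with `method = "median_mode"` and `drop_threshold`
#'   in (0, 1].
#' @param params A fitted `preprocess_params` from `fit_impute`.
#' @return `fit_impute`: a `preprocess_params`; `apply_impute`: the imputed
#'   cohort.
#' @export
fit_impute <- function(cohort, policy = list(method = "median_mode",
                                             drop_threshold = 0.5)) {
  if (nrow(cohort) == 0L) stop("cannot fit on an empty cohort", call. = FALSE)
  thr <- policy$drop_threshold %||% 0.5
  if (thr <= 0 || thr > 1) stop("drop_threshold must be in (0,1]", call. = FALSE)
  cols <- feature_cols(cohort)
  drop <- character(0)
  fill <- list()
  for (cl in cols) {
    v <- cohort[[cl]]
    frac <- mean(is.na(v))
    if (frac > thr) {
      drop <- c(drop, cl)
    } else if (all(is.na(v))) {
      stop(sprintf("column '%s' entirely missing and not droppable", cl),
           call. = FALSE)
    } else {
      fill[[cl]] <- if (is_categorical(v)) mode_of(v) else
        stats::median(v, na.rm = TRUE)
    }
  }
  structure(list(impute = list(drop = drop, fill = fill, threshold = thr)),
            class = "preprocess_params")
}

#' @rdname fit_impute
#' @export
apply_impute <- function(cohort, params) {
  check_fitted(params, "impute")
  cohort <- cohort[, setdiff(names(cohort), params$impute$drop), drop = FALSE]
  for (cl in names(params$impute$fill)) {
    if (!cl %in% names(cohort)) next
    miss <- is.na(cohort[[cl]])
    if (any(miss)) cohort[[cl]][miss] <- params$impute$fill[[cl]]
  }
  cohort
}

check_fitted <- function(params, what) {
  if (!inherits(params, "preprocess_params") || is.null(params[[what]])) {
    stop(sprintf("params not fitted for '%s'; call fit_%s first", what, what),
         call. = FALSE)
  }
}

#' Fit / apply categorical encoding
#'
#' One-hot (default): each categorical feature with c fitted levels expands
#' into c indicator columns named `feature.level`. Ordinal: levels map to
#' consecutive integers 0..c-1 in the order given by `ordinal_orders`. A
#' category unseen at fit time encodes as an all-zero indicator row (one-hot)
#' or -1 (ordinal), with a warning.
#'
#' @param cohort An imputed cohort data.frame (no missing feature cells).
#' @param scheme `"one_hot"` or `"ordinal"`.
#' @param ordinal_orders Named list, category order per categorical feature
#'   (required for `"ordinal"`).
#' @param params Fitted `preprocess_params` from `fit_encode`.
#' @param provenance Tag stored on the resulting [feature_matrix()].
#' @return `fit_encode`: a `preprocess_params`; `apply_encode`: a
#'   [feature_matrix()].
#' @export
fit_encode <- function(cohort, scheme = c("one_hot", "ordinal"),
                       ordinal_orders = NULL) {
  scheme <- match.arg(scheme)
  cols <- feature_cols(cohort)
  cat_cols <- cols[vapply(cohort[cols], is_categorical, logical(1))]
  levels <- lapply(cohort[cat_cols],
                   function(v) sort(unique(as.character(v[!is.na(v)]))))
  names(levels) <- cat_cols
  if (scheme == "ordinal") {
    missing_order <- setdiff(cat_cols, names(ordinal_orders %||% list()))
    if (length(missing_order) > 0) {
      stop("ordinal encoding needs an order for: ",
           paste(missing_order, collapse = ", "), call. = FALSE)
    }
    levels <- lapply(stats::setNames(cat_cols, cat_cols),
                     function(cl) ordinal_orders[[cl]])
  }
  structure(list(encode = list(scheme = scheme, levels = levels,
                               numeric_cols = setdiff(cols, cat_cols))),
            class = "preprocess_params")
}

#' @rdname fit_encode
#' @export
apply_encode <- function(cohort, params, provenance = "") {
  check_fitted(params, "encode")
  enc <- params$encode
  blocks <- list()
  for (cl in enc$numeric_cols) {
    if (!cl %in% names(cohort)) next
    blocks[[cl]] <- matrix(as.numeric(cohort[[cl]]), ncol = 1,
                           dimnames = list(NULL, cl))
  }
  for (cl in names(enc$levels)) {
    if (!cl %in% names(cohort)) next
    v <- as.character(cohort[[cl]])
    lv <- enc$levels[[cl]]
    unseen <- setdiff(unique(v), lv)
    if (length(unseen) > 0) {
      warning(sprintf("column '%s': unseen categor%s %s encoded as %s",
                      cl, if (length(unseen) > 1) "ies" else "y",
                      paste(unseen, collapse = ", "),
                      if (enc$scheme == "one_hot") "all-zero" else "-1"),
              call. = FALSE)
    }
    if (enc$scheme == "one_hot") {
      m <- vapply(lv, function(l) as.numeric(v == l), numeric(length(v)))
      if (length(v) == 1L) m <- matrix(m, nrow = 1)
      colnames(m) <- paste(cl, lv, sep = ".")
      blocks[[cl]] <- m
    } else {
      code <- match(v, lv) - 1
      code[is.na(code)] <- -1
      blocks[[cl]] <- matrix(code, ncol = 1, dimnames = list(NULL, cl))
    }
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- NULL
  y <- if ("diabetes" %in% names(cohort)) cohort$diabetes else
    integer(nrow(cohort))
  feature_matrix(x, y, provenance)
}

#' Fit / apply min-max scaling
#'
#' Per-column transform `(x - min) / (max - min)` with the min/max fitted
#' once; constant columns map to 0 and out-of-range values at apply time are
#' not clipped (a value above the fitted max scales above 1).
#'
#' @param fm A [feature_matrix()].
#' @param params Fitted `preprocess_params` from `fit_scale`.
#' @return `fit_scale`: a `preprocess_params`; `apply_scale`: the scaled
#'   [feature_matrix()].
#' @export
fit_scale <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  structure(list(scale = list(min = apply(fm$x, 2, min),
                              max = apply(fm$x, 2, max))),
            class = "preprocess_params")
}

#' @rdname fit_scale
#' @export
apply_scale <- function(fm, params) {
  stopifnot(inherits(fm, "feature_matrix"))
  check_fitted(params, "scale")
  sc <- params$scale
  cols <- colnames(fm$x)
  if (!all(cols %in% names(sc$min))) {
    stop("scaling params missing columns: ",
         paste(setdiff(cols, names(sc$min)), collapse = ", "), call. = FALSE)
  }
  rng <- sc$max[cols] - sc$min[cols]
  x <- sweep(fm$x, 2, sc$min[cols], "-")
  x <- sweep(x, 2, ifelse(rng == 0, 1, rng), "/")
  x[, rng == 0] <- 0
  feature_matrix(x, fm$y, fm$provenance)
}

#' Rebalance classes by undersampling the majority
#'
#' Keeps every minority-class row and subsamples majority rows without
#' replacement down to `ratio` majority rows per minority row (default 1:1).
#' Row order of the retained rows is preserved.
#'
#' @param fm A [feature_matrix()].
#' @param ratio Target majority:minority ratio (default 1).
#' @param seed Integer seed.
#' @return The rebalanced [feature_matrix()].
#' @export
undersample <- function(fm, ratio = 1, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  n1 <- sum(fm$y == 1L); n0 <- sum(fm$y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("undersampling needs both classes present", call. = FALSE)
  }
  minority <- if (n1 <= n0) 1L else 0L
  min_idx <- which(fm$y == minority)
  maj_idx <- which(fm$y != minority)
  target <- min(length(maj_idx), floor(length(min_idx) * ratio))
  keep_maj <- withr::with_seed(seed, sample(maj_idx, target))
  fm_subset(fm, sort(c(min_idx, keep_maj)))
}

#' Partition a feature matrix into client shards
#'
#' `"iid"`: random shuffle then a near-equal split (shard sizes differ by at
#' most one). `"label_skew"`: for each class, shard proportions are drawn
#' from a symmetric Dirichlet(`alpha`) and rows assigned accordingly —
#' smaller `alpha` gives stronger label skew across clients. Shards are
#' disjoint and their union is the input.
#'
#' @param fm A [feature_matrix()].
#' @param k Number of shards, `1 <= k <= nrow`.
#' @param mode `"iid"` or `"label_skew"`.
#' @param alpha Dirichlet concentration for `"label_skew"`.
#' @param seed Integer seed.
#' @return List of `k` [feature_matrix()] shards.
#' @export
partition_shards <- function(fm, k, mode = c("iid", "label_skew"),
                             alpha = 0.5, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  mode <- match.arg(mode)
  n <- nrow(fm$x)
  if (k < 1L || k > n) stop("k must be between 1 and nrow", call. = FALSE)
  assign <- withr::with_seed(seed, {
    if (mode == "iid") {
      sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
      sample(rep(seq_len(k), times = sizes))
    } else {
      a <- integer(n)
      for (cls in unique(fm$y)) {
        idx <- which(fm$y == cls)
        g <- stats::rgamma(k, shape = alpha)
        a[idx] <- sample(seq_len(k), length(idx), replace = TRUE,
                         prob = g / sum(g))
      }
      a
    }
  })
  lapply(seq_len(k), function(i) {
    idx <- which(assign == i)
    sh <- fm_subset(fm, idx)
    sh$provenance <- sprintf("%s/shard%d", fm$provenance, i)
    attr(sh, "indices") <- idx  # rows of the input behind this shard
    sh
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
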