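# Synthetic EHR cohort generator. Emulates the schema of a public diabetes
# prediction dataset (gender, age, hypertension, heart disease, smoking
# history, BMI, HbA1c, blood glucose, binary diabetes label) with a known
# logistic outcome model, so that downstream learning has a computable
# Bayes-optimal accuracy ceiling.

# Columns that may carry injected missingness; the label and id never do.
MASKABLE_COLUMNS <- c("gender", "age", "hypertension", "heart_disease",
                      "smoking_history", "bmi", "hba1c", "glucose")
COHORT_COLUMNS <- c("subject_id", MASKABLE_COLUMNS, "diabetes")

# Reference moments of the continuous feature marginals (frozen from a one-off
# 2e6-draw Monte-Carlo integration of the marginals below). Coefficients act
# on (x - mean) / sd, i.e. are per-SD log-odds contributions.
REFERENCE_MOMENTS <- list(
  age     = c(mean = 42.76, sd = 18.82),
  bmi     = c(mean = 27.55, sd = 5.57),
  hba1c   = c(mean = 5.73,  sd = 0.82),
  glucose = c(mean = 140.71, sd = 39.12)
)

#' Configuration of the synthetic cohort generator
#'
#' The outcome is Bernoulli with success probability
#' `plogis(intercept + sum(coefficients * z))`, where `z` holds the
#' standardized continuous features (age, BMI, HbA1c, glucose; frozen
#' reference moments) and the raw 0/1 comorbidity indicators. Gender and
#' smoking history are carried as realistic noise features and do not enter
#' the outcome model by default. When `intercept` is `NULL` it is calibrated
#' by bisection on a pilot draw so that the expected prevalence matches
#' `target_prevalence`.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param coefficients Named vector of log-odds weights over
#'   `age, bmi, hba1c, glucose, hypertension, heart_disease` (subset allowed).
#' @param intercept Log-odds intercept, or `NULL` to auto-calibrate.
#' @param target_prevalence Desired positive-label proportion in (0, 1).
#' @param missingness_rate Per-cell MCAR masking probability applied by
#'   [generate_cohort()] to the maskable columns.
#' @param gender_probs,smoking_probs Category probability vectors (must sum
#'   to 1 within 1e-9).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 10000L,
                             seed = 1L,
                             coefficients = c(hba1c = 1.6, glucose = 1.4,
                                              bmi = 0.6, age = 0.8,
                                              hypertension = 0.4,
                                              heart_disease = 0.3),
                             intercept = NULL,
                             target_prevalence = 0.10,
                             missingness_rate = 0,
                             gender_probs = c(female = 0.49, male = 0.49,
                                              other = 0.02),
                             smoking_probs = c(never = 0.36, former = 0.10,
                                               current = 0.10,
                                               `not-current` = 0.07,
                                               ever = 0.04, `no-info` = 0.33)) {
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("n must be a single non-negative count", call. = FALSE)
  }
  if (!all(is.finite(coefficients))) {
    stop("coefficients must all be finite", call. = FALSE)
  }
  unknown <- setdiff(names(coefficients),
                     c(names(REFERENCE_MOMENTS), "hypertension", "heart_disease"))
  if (length(unknown) > 0) {
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("target_prevalence must be in (0, 1)", call. = FALSE)
  }
  if (missingness_rate < 0 || missingness_rate > 1) {
    stop("missingness_rate must be in [0, 1]", call. = FALSE)
  }
  for (p in list(gender_probs, smoking_probs)) {
    if (abs(sum(p) - 1) > 1e-9) {
      stop("category probabilities must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         coefficients = coefficients, intercept = intercept,
         target_prevalence = target_prevalence,
         missingness_rate = missingness_rate,
         gender_probs = gender_probs, smoking_probs = smoking_probs),
    class = "generator_config"
  )
}

# inverse-CDF truncated normal draw: deterministic given the RNG stream
rtrunc_norm <- function(n, mean, sd, lower, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

# draw raw features only (no labels); returns a data.frame
draw_features <- function(config, n, seed) {
  withr::with_seed(seed, {
    gender <- sample(names(config$gender_probs), n, replace = TRUE,
                     prob = config$gender_probs)
    smoking <- sample(names(config$smoking_probs), n, replace = TRUE,
                      prob = config$smoking_probs)
    age <- rtrunc_norm(n, 42, 20, 0, 100)
    bmi <- stats::rlnorm(n, log(27), 0.2)
    elevated <- stats::runif(n) < 0.15
    hba1c <- rtrunc_norm(n, ifelse(elevated, 7, 5.5),
                         ifelse(elevated, 0.9, 0.55), 3)
    glucose <- rtrunc_norm(n, 140, 40, 40)
    hypertension <- stats::rbinom(n, 1L, 0.08)
    heart_disease <- stats::rbinom(n, 1L, 0.04)
    data.frame(gender = gender, age = age, hypertension = hypertension,
               heart_disease = heart_disease, smoking_history = smoking,
               bmi = bmi, hba1c = hba1c, glucose = glucose,
               stringsAsFactors = FALSE)
  })
}

# linear predictor without intercept, on standardized continuous features
linear_score <- function(config, feats) {
  z <- rep(0, nrow(feats))
  for (nm in names(config$coefficients)) {
    x <- feats[[nm]]
    if (nm %in% names(REFERENCE_MOMENTS)) {
      m <- REFERENCE_MOMENTS[[nm]]
      x <- (x - m[["mean"]]) / m[["sd"]]
    }
    z <- z + config$coefficients[[nm]] * x
  }
  z
}

# Calibrate the intercept by bisection so that mean(plogis(b0 + score)) on a
# pilot draw hits target_prevalence (tolerance 0.002 in prevalence).
calibrate_intercept <- function(config, pilot_n = 100000L, tol = 0.002) {
  pilot <- draw_features(config, pilot_n,
                         seed = bitwAnd(config$seed + 990001L, 0x7fffffffL))
  score <- linear_score(config, pilot)
  f <- function(b0) mean(stats::plogis(b0 + score)) - config$target_prevalence
  lo <- -30; hi <- 30
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) <= tol) return(mid)
    if (v > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

resolved_intercept <- function(config) {
  if (!is.null(config$intercept)) config$intercept else calibrate_intercept(config)
}

#' Generate a synthetic patient cohort
#'
#' Draws `config$n` patient records from the generator's marginals, assigns
#' labels from the logistic outcome model, and applies MCAR missingness at
#' `config$missingness_rate`. Byte-identical output for identical config.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns
#'   `subject_id, gender, age, hypertension, heart_disease, smoking_history,
#'   bmi, hba1c, glucose, diabetes`; the attribute `"intercept"` records the
#'   (possibly calibrated) intercept actually used.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  if (n == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), list(character(0)), list(numeric(0)),
        list(integer(0)), list(integer(0)), list(character(0)),
        list(numeric(0)), list(numeric(0)), list(numeric(0)),
        list(integer(0))), COHORT_COLUMNS))
    attr(out, "intercept") <- if (is.null(config$intercept)) NA_real_ else config$intercept
    return(out)
  }
  b0 <- resolved_intercept(config)
  feats <- draw_features(config, n, seed = config$seed)
  p <- stats::plogis(b0 + linear_score(config, feats))
  labels <- withr::with_seed(bitwAnd(config$seed + 77L, 0x7fffffffL),
                             stats::rbinom(n, 1L, p))
  cohort <- cbind(
    data.frame(subject_id = sprintf("S%06d", seq_len(n)),
               stringsAsFactors = FALSE),
    feats,
    data.frame(diabetes = labels)
  )
  if (config$missingness_rate > 0) {
    cohort <- inject_missingness(cohort, config$missingness_rate,
                                 seed = bitwAnd(config$seed + 7919L, 0x7fffffffL))
  }
  attr(cohort, "intercept") <- b0
  cohort
}

#' Monte-Carlo Bayes accuracy of the generator
#'
#' Estimates the accuracy of the Bayes decision rule "predict positive iff
#' the true model probability is at least 0.5" by drawing `n_mc` fresh
#' subjects and labels from the generator. This is the ceiling that no
#' classifier trained on cohorts from the same config can beat (up to Monte
#' Carlo error).
#'
#' @param config A [generator_config()].
#' @param n_mc Number of Monte-Carlo draws (at least 1000).
#' @param seed Integer seed for the draw.
#' @return Estimated accuracy in `[0, 1]`, with attribute `"se"` holding the
#'   binomial standard error.
#' @export
bayes_accuracy <- function(config, n_mc = 100000L, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  if (n_mc < 1000L) stop("n_mc must be at least 1000", call. = FALSE)
  b0 <- resolved_intercept(config)
  feats <- draw_features(config, n_mc, seed = seed)
  p <- stats::plogis(b0 + linear_score(config, feats))
  y <- withr::with_seed(bitwAnd(seed + 77L, 0x7fffffffL),
                        stats::rbinom(n_mc, 1L, p))
  acc <- mean((p >= 0.5) == (y == 1L))
  attr(acc, "se") <- sqrt(acc * (1 - acc) / n_mc)
  acc
}

#' Inject missing-completely-at-random cells
#'
#' Masks each maskable cell (all feature columns; never `subject_id` or the
#' `diabetes` label) independently with probability `rate`.
#'
#' @param cohort A cohort data.frame.
#' @param rate Masking probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The cohort with masked cells set to `NA`.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (rate == 0 || nrow(cohort) == 0L) return(cohort)
  cols <- intersect(MASKABLE_COLUMNS, names(cohort))
  withr::with_seed(seed, {
    for (cl in cols) {
      mask <- stats::runif(nrow(cohort)) < rate
      cohort[[cl]][mask] <- NA
    }
  })
  cohort
}

#' Write / read a cohort CSV
#'
#' Fixed header `subject_id, gender, ..., diabetes`; missing cells are
#' encoded as empty strings. The writer is byte-deterministic, so identical
#' configs yield identical files.
#'
#' @param cohort A cohort data.frame.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(format_cohort(cohort), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

format_cohort <- function(cohort) {
  out <- cohort
  for (cl in c("age", "bmi", "hba1c", "glucose")) {
    if (cl %in% names(out)) out[[cl]] <- sprintf("%.6f", out[[cl]])
  }
  out[is.na(cohort)] <- ""
  out
}

#' Serialized size of a cohort in CSV form
#'
#' Byte count of the cohort's CSV serialization (header included), used as
#' the per-client upload cost of centralized learning in the communication
#' report.
#'
#' @param cohort A cohort data.frame.
#' @return Number of bytes.
#' @export
cohort_serialized_bytes <- function(cohort) {
  lines <- utils::capture.output(
    utils::write.csv(format_cohort(cohort), row.names = FALSE,
                     quote = FALSE, na = ""))
  sum(nchar(lines, type = "bytes") + 1L)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = NA)
  for (cl in c("age", "bmi", "hba1c", "glucose")) {
    if (cl %in% names(df)) df[[cl]] <- as.numeric(df[[cl]])
  }
  for (cl in c("hypertension", "heart_disease", "diabetes")) {
    if (cl %in% names(df)) df[[cl]] <- as.integer(df[[cl]])
  }
  df
}
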