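# Validation protocol: repeated stratified 60/40 split trials, selection of
# the optimal trial model, and reliability resampling of a trained model.

#' Stratified train/test split
#'
#' Splits patients into train and test sets separately within each label
#' stratum: `round(ratio * stratum size)` patients (round-half-up) are
#' sampled without replacement into the training set, the rest form the test
#' set. With strata of 126 and 136 at ratio 0.6 the training set takes 76
#' and 82 patients respectively.
#'
#' @param labels Binary stratum labels (0/1), one per patient.
#' @param ratio Training fraction in (0, 1).
#' @param seed RNG seed; the split is a deterministic function of
#'   `(labels, ratio, seed)`.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all patients).
#' @export
stratified_split <- function(labels, ratio, seed) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  idx <- seq_along(labels)
  train <- integer(0)
  with_seed(seed, {
    for (g in sort(unique(labels))) {
      pool <- idx[labels == g]
      if (length(pool) < 2L) stop("stratum smaller than 2")
      n_take <- floor(ratio * length(pool) + 0.5)  # round half up
      if (n_take < 1L || n_take >= length(pool)) {
        stop("ratio leaves an empty train or test stratum")
      }
      train <- c(train, sample(pool, n_take))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(idx, train))
}

#' Repeated stratified split trials
#'
#' The cross-validation protocol: in each trial the cohort is split 60/40
#' within the short- and long-term strata, the stratifier is retrained from
#' scratch on the training split (with a trial-specific seed derived from
#' the master seed), the test split is stratified by the trained model, and
#' the two predicted groups are compared by log-rank test. A trial whose
#' test split gets a single predicted group records p = 1 with a warning.
#'
#' @param x Raw valid-feature matrix (patients x features).
#' @param labels Cluster-derived 0/1 labels (1 = long-term).
#' @param os_days,os_event Survival data aligned to rows of `x`.
#' @param config A [neodl_config()]; `n_trials`, `split_ratio` and the model
#'   settings are taken from it.
#' @param scaler Cohort-level scaler carried into every trial model.
#' @param keep_models Keep each trial's trained model (memory-heavy); the
#'   best model is always retained.
#' @return List with `trials` (data frame: `trial`, `seed`, `n_train`,
#'   `n_test`, `logrank_p`, `auc`, `significant`), `best_model`,
#'   `best_trial`, and `models` (when kept).
#' @export
run_split_trials <- function(x, labels, os_days, os_event,
                             config = neodl_config(), scaler = NULL,
                             keep_models = FALSE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(os_days))
  if (is.null(scaler)) scaler <- zscaler_fit(x)
  n_trials <- config$n_trials
  rows <- vector("list", n_trials)
  models <- if (keep_models) vector("list", n_trials) else NULL
  best_model <- NULL
  best_p <- Inf
  best_trial <- NA_integer_
  for (i in seq_len(n_trials)) {
    trial_seed <- (config$seed + i) %% .Machine$integer.max
    sp <- stratified_split(labels, config$split_ratio, trial_seed)
    model <- train_neodl(x[sp$train, , drop = FALSE], labels[sp$train],
                         config, scaler = scaler, seed = trial_seed)
    pred <- predict(model, x[sp$test, , drop = FALSE])
    if (length(unique(pred$label)) < 2L) {
      warning("trial ", i, ": one predicted group is empty; recording p = 1")
      p <- 1
    } else {
      p <- logrank_test(os_days[sp$test], os_event[sp$test],
                        pred$label)$p
    }
    auc <- if (length(unique(labels[sp$test])) == 2L) {
      auc_score(labels[sp$test], pred$probability)
    } else NA_real_
    rows[[i]] <- data.frame(trial = i, seed = trial_seed,
                            n_train = length(sp$train),
                            n_test = length(sp$test), logrank_p = p,
                            auc = auc, significant = p < 0.05)
    if (keep_models) models[[i]] <- model
    if (p < best_p) {  # strict: ties keep the earlier trial
      best_p <- p
      best_model <- model
      best_trial <- i
    }
  }
  list(trials = do.call(rbind, rows), best_model = best_model,
       best_trial = best_trial, models = models)
}

#' Select the optimal trial model
#'
#' The model of the trial with the smallest test log-rank p; ties resolve to
#' the lowest trial index.
#'
#' @param trials Result of [run_split_trials()] (needs `keep_models = TRUE`,
#'   or falls back to the retained best model).
#' @return A `neodl_model`.
#' @export
select_optimal_model <- function(trials) {
  if (!is.null(trials$models)) {
    trials$models[[which.min(trials$trials$logrank_p)]]
  } else if (!is.null(trials$best_model)) {
    trials$best_model
  } else {
    stop("no models retained in the trial results")
  }
}

#' Reliability resampling of a trained model
#'
#' Applies a fixed trained model to repeated simple random subsamples of the
#' cohort (unstratified, default 60%), testing each time whether the
#' predicted groups differ in survival.
#'
#' @param model A trained `neodl_model`.
#' @param x Raw valid-feature matrix.
#' @param os_days,os_event Survival data.
#' @param fraction Subsample fraction.
#' @param reps Number of repeats.
#' @param seed Master seed.
#' @return List with `n_significant`, `reps`, and the per-rep `p` values.
#' @export
reliability_resampling <- function(model, x, os_days, os_event,
                                   fraction = 0.6, reps = 300L,
                                   seed = 20210723L) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- max(2L, min(n, floor(fraction * n + 0.5)))
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    sel <- with_seed((seed + r) %% .Machine$integer.max, sample(n, m))
    pred <- predict(model, x[sel, , drop = FALSE])
    ps[r] <- if (length(unique(pred$label)) < 2L) 1 else {
      logrank_test(os_days[sel], os_event[sel], pred$label)$p
    }
  }
  list(n_significant = sum(ps < 0.05), reps = reps, p = ps)
}

#' Write a trial report
#'
#' @param trials Result of [run_split_trials()].
#' @param path Output TSV path.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
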