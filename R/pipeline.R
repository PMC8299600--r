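# Full pipeline: featurize -> aggregate -> screen -> z-score -> cluster ->
# train -> validate, presented as a single model-fitting function with the
# usual methods.

#' Fit the neoDL survival stratification pipeline
#'
#' Runs the whole analysis on a cohort: neoantigen calling by the 500 nM
#' rule, intrinsic featurization of the called pairs, per-patient averaging,
#' univariate Cox screening for valid features, z-scoring, hierarchical
#' k-means survival labelling, repeated stratified split validation of the
#' LSTM stratifier, and final model selection.
#'
#' @param cohort A [neo_cohort()].
#' @param config A [neodl_config()].
#' @param keep_models Keep every trial model (see [run_split_trials()]).
#' @return Object of class `neodl`: `features` (per-patient matrix),
#'   `screening`, `valid`, `scaler`, `cluster`, `semantics`, `labels`,
#'   `trials`, `model`, `auc`, `logrank`, `patients`, `survival`, `config`.
#' @seealso [predict.neodl()], [baseline_stratifiers()]
#' @export
neodl <- function(cohort, config = neodl_config(), keep_models = FALSE) {
  stopifnot(inherits(cohort, "neo_cohort"))
  called <- call_neoantigens(cohort$pairs)
  if (nrow(called) == 0L) {
    stop("featurization: no pairs pass the neoantigen-calling filter")
  }
  pf <- featurize_pairs(called)
  pm <- aggregate_patients(pf)
  clin <- cohort$clinical[match(rownames(pm), cohort$clinical$patient_id), ]
  screening <- select_valid_features(pm, clin$os_days, clin$os_event,
                                     alpha = config$alpha,
                                     max_features = config$max_features)
  if (length(screening$valid) < 2L) {
    stop("screening: fewer than two valid features")
  }
  xv <- pm[, screening$valid, drop = FALSE]
  scaler <- zscaler_fit(xv)
  z <- impute_masked(zscaler_apply(scaler, xv))
  lab <- survival_labels(z, clin$os_days, k = config$k)
  trials <- run_split_trials(xv, lab$labels, clin$os_days, clin$os_event,
                             config, scaler = scaler,
                             keep_models = keep_models)
  model <- if (config$model_mode == "full") {
    train_neodl(xv, lab$labels, config, scaler = scaler)
  } else {
    trials$best_model
  }
  pred <- predict(model, xv)
  auc <- auc_score(lab$labels, pred$probability)
  lr <- if (length(unique(pred$label)) == 2L) {
    logrank_test(clin$os_days, clin$os_event, pred$label)
  } else {
    list(chi2 = NA_real_, p = NA_real_)
  }
  structure(list(
    features = pm, screening = screening, valid = screening$valid,
    scaler = scaler, cluster = lab$cluster, semantics = lab$semantics,
    labels = lab$labels, trials = trials, model = model,
    prediction = cbind(patient_id = rownames(pm), pred), auc = auc,
    logrank = lr, patients = rownames(pm),
    survival = data.frame(patient_id = rownames(pm),
                          os_days = clin$os_days, os_event = clin$os_event),
    cohort_name = cohort$name, config = config), class = "neodl")
}

#' @export
print.neodl <- function(x, ...) {
  tr <- x$trials$trials
  cat("neoDL fit on '", x$cohort_name, "': ", length(x$patients),
      " patients with called neoantigens\n", sep = "")
  cat("  valid features: ", length(x$valid), " / ",
      nrow(x$screening$table), " screened (p <= ", x$config$alpha, ")\n",
      sep = "")
  cat("  clusters: ",
      paste(sprintf("%s (n = %d)", x$semantics,
                    tabulate(x$cluster, length(x$semantics))),
            collapse = ", "), "\n", sep = "")
  cat("  split trials: ", sum(tr$significant), " / ", nrow(tr),
      " significant (log-rank p < 0.05)\n", sep = "")
  cat("  full-cohort AUC vs cluster labels: ", round(x$auc, 3),
      "; log-rank p = ", signif(x$logrank$p, 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.neodl <- function(object, ...) {
  tr <- object$trials$trials
  out <- list(
    n_patients = length(object$patients),
    n_valid_features = length(object$valid),
    cluster_sizes = tabulate(object$cluster, length(object$semantics)),
    semantics = object$semantics,
    n_trials = nrow(tr),
    n_significant_trials = sum(tr$significant),
    median_trial_p = stats::median(tr$logrank_p),
    median_trial_auc = stats::median(tr$auc, na.rm = TRUE),
    best_trial = object$trials$best_trial,
    auc = object$auc, logrank_p = object$logrank$p,
    top_features = utils::head(
      object$screening$table[order(object$screening$table$p), ], 10L))
  class(out) <- "summary.neodl"
  out
}

#' @export
print.summary.neodl <- function(x, ...) {
  cat("neoDL pipeline summary\n")
  cat("  patients: ", x$n_patients, "; valid features: ",
      x$n_valid_features, "\n", sep = "")
  cat("  clusters: ", paste(sprintf("%s (n = %d)", x$semantics,
                                    x$cluster_sizes), collapse = ", "),
      "\n", sep = "")
  cat("  trials: ", x$n_significant_trials, "/", x$n_trials,
      " significant; median p = ", signif(x$median_trial_p, 3),
      "; median AUC = ", round(x$median_trial_auc, 3), "\n", sep = "")
  cat("  final model: AUC = ", round(x$auc, 3), ", log-rank p = ",
      signif(x$logrank_p, 3), "\n", sep = "")
  cat("  top screened features:\n")
  print(x$top_features[, c("feature", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' Screening coefficients of a fitted pipeline
#'
#' @param object A fitted `neodl` object.
#' @param valid_only Restrict to the valid features.
#' @param ... Unused.
#' @return Named vector of per-feature Cox log-hazard coefficients.
#' @export
coef.neodl <- function(object, valid_only = TRUE, ...) {
  tab <- object$screening$table
  if (valid_only) tab <- tab[tab$valid, ]
  stats::setNames(tab$beta, tab$feature)
}

#' Apply a fitted pipeline to a new cohort
#'
#' External-validation mode: the new cohort's pairs are called and
#' featurized with the same vocabulary, aggregated per patient, restricted
#' to the training valid features, passed through the training z-scaler and
#' the trained model. When the new cohort carries survival data the
#' predicted groups are compared by log-rank test.
#'
#' @param object A fitted `neodl`.
#' @param newdata A [neo_cohort()] (or a raw per-patient feature matrix
#'   containing the valid-feature columns).
#' @param ... Unused.
#' @return List with `prediction` (per-patient probabilities and labels) and
#'   `logrank` (when survival data are available).
#' @export
predict.neodl <- function(object, newdata, ...) {
  if (inherits(newdata, "neo_cohort")) {
    called <- call_neoantigens(newdata$pairs)
    if (nrow(called) == 0L) stop("no called neoantigens in new cohort")
    pm <- aggregate_patients(featurize_pairs(called))
    clin <- newdata$clinical[match(rownames(pm),
                                   newdata$clinical$patient_id), ]
  } else {
    pm <- as.matrix(newdata)
    clin <- NULL
  }
  miss <- setdiff(object$valid, colnames(pm))
  if (length(miss)) stop("new data lack valid features: ",
                         paste(utils::head(miss, 3L), collapse = ", "))
  xv <- pm[, object$valid, drop = FALSE]
  pred <- predict(object$model, xv)
  pred <- cbind(patient_id = rownames(pm), pred)
  lr <- NULL
  if (!is.null(clin) && length(unique(pred$label)) == 2L) {
    lr <- logrank_test(clin$os_days, clin$os_event, pred$label)
  }
  list(prediction = pred, logrank = lr)
}

#' Kaplan-Meier plot of the fitted stratification
#'
#' Survival curves of the model-predicted groups on the training cohort
#' (base graphics, in the style of the usual KM displays: long-term blue,
#' short-term red).
#'
#' @param x A fitted `neodl`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.neodl <- function(x, ...) {
  grp <- factor(x$prediction$label, levels = c(0, 1),
                labels = c("short-term", "long-term"))
  fit <- survival::survfit(
    survival::Surv(x$survival$os_days, x$survival$os_event) ~ grp)
  graphics::plot(fit, col = c("red", "blue"), xlab = "Days",
                 ylab = "Survival probability", mark.time = TRUE, ...)
  graphics::legend("topright", legend = levels(grp),
                   col = c("red", "blue"), lty = 1, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", x$logrank$p), side = 3,
                  line = 0.2, cex = 0.9)
  invisible(x)
}

#' Baseline survival stratifiers
#'
#' The three reference stratifiers the intrinsic-feature model is compared
#' against: per-patient missense mutational load, neoantigen count and mean
#' DAI, each dichotomized at its cohort mean and evaluated by log-rank test.
#'
#' @param cohort A [neo_cohort()]; the mutation table is optional (the
#'   missense-load baseline is skipped without it).
#' @return Data frame with one row per baseline: `baseline`, `n`, `n_high`,
#'   `n_low`, `chi2`, `p`.
#' @export
baseline_stratifiers <- function(cohort) {
  clin <- cohort$clinical
  vals <- list()
  if (!is.null(cohort$mutations)) {
    vals$missense_load <- missense_load(cohort)
  }
  vals$neoantigen_count <- neoantigen_count(cohort)
  dai <- patient_mean_dai(cohort)
  vals$mean_dai <- stats::setNames(
    as.numeric(dai[match(clin$patient_id, names(dai))]), clin$patient_id)
  rows <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    keep <- is.finite(v)
    cl <- clin[match(names(v)[keep], clin$patient_id), ]
    ms <- mean_split_stratify(v[keep], cl$os_days, cl$os_event)
    data.frame(baseline = nm, n = sum(keep), n_high = sum(ms$high),
               n_low = sum(ms$low), chi2 = ms$logrank$chi2,
               p = ms$logrank$p)
  })
  do.call(rbind, rows)
}
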