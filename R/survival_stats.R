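# Survival statistics: proportional-hazards screening, Kaplan-Meier and
# log-rank evaluation, mean-split baselines and group comparisons. Model
# fitting is delegated to the survival package (Efron tie handling).

.check_surv <- function(os_days, os_event) {
  stopifnot(length(os_days) == length(os_event))
  if (length(os_days) < 2L) stop("need at least 2 patients")
  if (any(!is.finite(os_days)) || any(!os_event %in% c(0, 1))) {
    stop("os_days must be finite and os_event binary")
  }
  if (sum(os_event) < 1) stop("need at least one event")
  invisible(TRUE)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit of a single feature against overall survival with
#' Efron tie handling and a Wald p-value.
#'
#' @param x Numeric feature values, one per patient.
#' @param os_days,os_event Survival time (days) and event indicator (1 =
#'   death, 0 = censored).
#' @return List with `beta`, `hr`, `p`, `ci95` (vector low/high on the HR
#'   scale), `n`, `converged`. Zero-variance features are returned with
#'   `converged = FALSE` and `NA` statistics.
#' @export
cox_univariate <- function(x, os_days, os_event) {
  .check_surv(os_days, os_event)
  keep <- is.finite(x)
  x <- x[keep]
  os_days <- os_days[keep]
  os_event <- os_event[keep]
  n <- length(x)
  if (n < 2L || stats::var(x) == 0 || sum(os_event) < 1) {
    return(list(beta = NA_real_, hr = NA_real_, p = NA_real_,
                ci95 = c(NA_real_, NA_real_), n = n, converged = FALSE))
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(os_days, os_event) ~ x, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit)[1])) {
    return(list(beta = NA_real_, hr = NA_real_, p = NA_real_,
                ci95 = c(NA_real_, NA_real_), n = n, converged = FALSE))
  }
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(stats::vcov(fit)))[1]
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  list(beta = beta, hr = exp(beta), p = p,
       ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se), n = n,
       converged = is.finite(se) && se > 0)
}

#' Covariate-adjusted Cox fit
#'
#' Multivariate Efron fit of a feature plus covariates (for example age and
#' mutational load). Non-identifiable coefficients (collinear covariates) are
#' flagged through `converged = FALSE`.
#'
#' @param x Feature values.
#' @param covariates Data frame or matrix of covariate columns.
#' @inheritParams cox_univariate
#' @return List with per-term `beta`, `hr`, `se`, `p` (feature first, named
#'   `x`), `n` and `converged`.
#' @export
cox_adjusted <- function(x, covariates, os_days, os_event) {
  .check_surv(os_days, os_event)
  covariates <- as.data.frame(covariates)
  dat <- data.frame(x = x, covariates, os_days = os_days,
                    os_event = os_event)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fml <- stats::as.formula(paste(
    "survival::Surv(os_days, os_event) ~ x +",
    paste(colnames(covariates), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = dat, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(beta = NULL, hr = NULL, se = NULL, p = NULL, n = nrow(dat),
                converged = FALSE))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  p <- 2 * stats::pnorm(-abs(beta / se))
  list(beta = beta, hr = exp(beta), se = se, p = p, n = nrow(dat),
       converged = all(is.finite(beta)) && all(is.finite(se)))
}

#' Screen features for prognostic value
#'
#' Univariate Cox fit of every feature column against survival; features with
#' Wald p below the threshold are the "valid" features carried into
#' clustering and model training. No multiplicity correction is applied by
#' default (set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param features Patients x features numeric matrix.
#' @param os_days,os_event Survival data aligned to the rows of `features`.
#' @param alpha Selection threshold on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param max_features Optional cap: keep at most this many valid features,
#'   smallest p first (vocabulary order is restored afterwards).
#' @return List with `table` (one row per feature: `feature`, `beta`, `hr`,
#'   `p`, `ci_low`, `ci_high`, `valid`) and `valid` (selected names in
#'   vocabulary order).
#' @export
select_valid_features <- function(features, os_days, os_event, alpha = 0.05,
                                  adjust = c("none", "BH"),
                                  max_features = Inf) {
  adjust <- match.arg(adjust)
  .check_surv(os_days, os_event)
  stopifnot(nrow(features) == length(os_days))
  fits <- lapply(seq_len(ncol(features)), function(j) {
    cox_univariate(features[, j], os_days, os_event)
  })
  tab <- data.frame(
    feature = colnames(features),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    hr = vapply(fits, `[[`, numeric(1), "hr"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    ci_low = vapply(fits, function(f) f$ci95[1], numeric(1)),
    ci_high = vapply(fits, function(f) f$ci95[2], numeric(1)),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  psel <- if (adjust == "BH") stats::p.adjust(tab$p, "BH") else tab$p
  tab$valid <- tab$converged & !is.na(psel) & psel <= alpha
  if (is.finite(max_features) && sum(tab$valid) > max_features) {
    ord <- order(tab$p)
    keep <- ord[tab$valid[ord]][seq_len(max_features)]
    tab$valid <- seq_len(nrow(tab)) %in% keep
  }
  if (!any(tab$valid)) warning("no valid features at alpha = ", alpha)
  list(table = tab, valid = tab$feature[tab$valid])
}

#' Correlation matrix of selected features
#'
#' Pearson correlations between feature columns; zero-variance columns give
#' `NA` entries (masked), the diagonal is 1 for well-defined columns.
#'
#' @param features Patients x features matrix.
#' @param select Optional character vector of columns to use.
#' @return Symmetric correlation matrix.
#' @export
feature_correlation_matrix <- function(features, select = NULL) {
  if (!is.null(select)) features <- features[, select, drop = FALSE]
  if (ncol(features) < 2L) stop("need at least two features")
  suppressWarnings(stats::cor(features, use = "pairwise.complete.obs"))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function.
#'
#' @inheritParams cox_univariate
#' @return Data frame `time`, `survival`, `n_at_risk` (step function,
#'   starting at 1, non-increasing).
#' @export
km_estimate <- function(os_days, os_event) {
  .check_surv(os_days, os_event)
  fit <- survival::survfit(survival::Surv(os_days, os_event) ~ 1)
  data.frame(time = fit$time, survival = fit$surv, n_at_risk = fit$n.risk)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square with 1 degree of freedom. For
#' extreme statistics the p-value is floored at the smallest positive double.
#'
#' @param os_days,os_event Survival data for both groups combined.
#' @param group Two-level grouping vector.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(os_days, os_event, group) {
  .check_surv(os_days, os_event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) {
    stop("log-rank test requires exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(os_days, os_event) ~ group)
  chi2 <- sd$chisq
  p <- max(stats::pchisq(chi2, df = 1, lower.tail = FALSE),
           .Machine$double.xmin)
  list(chi2 = chi2, p = p)
}

#' Mean-split survival stratification
#'
#' Dichotomizes a per-patient score at its mean (high: value > mean; low:
#' value <= mean, so ties go to the low group) and compares the two survival
#' curves by log-rank test. This is the baseline stratifier used with
#' missense load, neoantigen count and mean DAI.
#'
#' @param values Per-patient scores.
#' @inheritParams cox_univariate
#' @return List with `high` and `low` (logical masks), `threshold` (the
#'   mean) and `logrank` (list `chi2`, `p`).
#' @export
mean_split_stratify <- function(values, os_days, os_event) {
  if (any(!is.finite(values))) stop("values must be finite")
  thr <- mean(values)
  high <- values > thr
  if (!any(high) || all(high)) {
    stop("mean split produced an empty group (all values equal?)")
  }
  lr <- logrank_test(os_days, os_event, ifelse(high, "high", "low"))
  list(high = high, low = !high, threshold = thr, logrank = lr)
}

#' Unpaired two-sample comparison
#'
#' Welch unpaired t-test of two groups of feature values.
#'
#' @param a,b Numeric vectors.
#' @return List with `t`, `p`, `df`, and the two group means.
#' @export
group_compare <- function(a, b) {
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Write a screening report
#'
#' @param screening Result of [select_valid_features()].
#' @param path Output TSV path.
#' @export
write_screening <- function(screening, path) {
  utils::write.table(screening$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export Kaplan-Meier curves for plotting
#'
#' @param os_days,os_event Survival data.
#' @param group Grouping vector.
#' @return Data frame `time`, `survival`, `n_at_risk`, `group`.
#' @export
km_export <- function(os_days, os_event, group) {
  group <- as.character(group)
  out <- lapply(unique(group), function(g) {
    sel <- group == g
    cbind(km_estimate(os_days[sel], os_event[sel]), group = g)
  })
  do.call(rbind, out)
}
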