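# Synthetic cohorts with the statistical structure the pipeline assumes:
# per-patient sets of MT/WT 9-mer pairs with a single-residue difference,
# IC50 pairs straddling the 500 nM calling rule, and right-censored survival
# whose hazard depends on a planted two-group structure. The groups are
# encoded compositionally: the long-term group's peptides are enriched for
# R and S at positions 3-4 (heavier, more polar units), the short-term group
# for L and G (lighter); survival follows a proportional-hazards model on
# the group indicator.

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort: 200 patients, on average 8 pairs
#' each, exponential baseline hazard 1/400 per day with uniform censoring on
#' (0, 1500] days, group log-hazard difference log(3), residue-bias weight
#' 0.5 at positions 3-4, and 80% of emitted pairs passing the 500 nM rule.
#'
#' @param n_patients Number of patients (split evenly into the two groups).
#' @param lambda Poisson mean of pairs per patient (minimum 1).
#' @param beta Log hazard ratio between short- and long-term groups.
#' @param h0 Baseline hazard per day (geometric mean across groups).
#' @param censor_window Upper bound of the uniform censoring time (days).
#' @param bias Mixture weight added to the biased residues at positions 3-4
#'   (0 = no planted compositional signal).
#' @param prop_pass Probability that an emitted pair satisfies the calling
#'   rule (the rest violate it, to exercise the filter).
#' @param seed RNG seed; all outputs are deterministic functions of the
#'   configuration including the seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200L, lambda = 8, beta = log(3),
                       h0 = 1 / 400, censor_window = 1500,
                       bias = 0.5, prop_pass = 0.8, seed = 20210723L) {
  stopifnot(n_patients >= 4L, lambda > 0, h0 > 0, censor_window > 0,
            bias >= 0, bias <= 1, prop_pass > 0, prop_pass <= 1)
  structure(list(n_patients = as.integer(n_patients), lambda = lambda,
                 beta = beta, h0 = h0, censor_window = censor_window,
                 bias = bias, prop_pass = prop_pass,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw one residue per row from the background (uniform) distribution with
# an added mixture toward `enrich` at biased positions.
.draw_residues <- function(n, enrich = NULL, bias = 0) {
  if (is.null(enrich) || bias == 0) {
    AA20[sample.int(20L, n, replace = TRUE)]
  } else {
    use_bias <- stats::runif(n) < bias
    out <- AA20[sample.int(20L, n, replace = TRUE)]
    out[use_bias] <- enrich[sample.int(length(enrich), sum(use_bias),
                                       replace = TRUE)]
    out
  }
}

#' Generate peptide pairs
#'
#' Wild-type 9-mers are drawn residue-wise from a uniform background, with
#' an optional enrichment mixture at positions 3-4; the mutant differs at
#' exactly one uniformly drawn position. IC50 values are log-normal, drawn
#' conditionally so that each pair satisfies or violates the 500 nM calling
#' rule as decided by a `prop_pass` coin flip.
#'
#' @param n Number of pairs.
#' @param patient_id Patient id(s) to assign (recycled).
#' @param enrich Residues enriched at positions 3-4 (`NULL` for none).
#' @param bias Enrichment mixture weight.
#' @param prop_pass Probability a pair passes the calling rule.
#' @return Peptide-pair data frame (passes [validate_pairs()]).
#' @export
generate_peptide_pairs <- function(n, patient_id = "P1", enrich = NULL,
                                   bias = 0, prop_pass = 0.8) {
  wt <- matrix("", n, 9L)
  for (p in 1:9) {
    wt[, p] <- if (p %in% 3:4) .draw_residues(n, enrich, bias)
               else .draw_residues(n)
  }
  pos <- sample.int(9L, n, replace = TRUE)
  mt <- wt
  for (i in seq_len(n)) {
    cur <- wt[i, pos[i]]
    mt[i, pos[i]] <- sample(setdiff(AA20, cur), 1L)
  }
  pass <- stats::runif(n) < prop_pass
  # lognormal affinities conditioned on which side of 500 nM they must fall
  draw_trunc <- function(k, meanlog, lower, upper) {
    out <- numeric(k)
    todo <- seq_len(k)
    while (length(todo)) {
      x <- stats::rlnorm(length(todo), meanlog, 1)
      ok <- x > lower & x < upper
      out[todo[ok]] <- x[ok]
      todo <- todo[!ok]
    }
    out
  }
  ic50_mt <- ic50_wt <- numeric(n)
  n_pass <- sum(pass)
  if (n_pass) {
    ic50_mt[pass] <- draw_trunc(n_pass, log(150), 0, 500)
    ic50_wt[pass] <- draw_trunc(n_pass, log(1500), 500, Inf)
  }
  if (any(!pass)) {
    # violators: strong wild-type binder, so the pair is filtered out
    ic50_mt[!pass] <- stats::rlnorm(n - n_pass, log(300), 1)
    ic50_wt[!pass] <- draw_trunc(n - n_pass, log(200), 0, 500)
  }
  data.frame(patient_id = rep_len(as.character(patient_id), n),
             mt_peptide = apply(mt, 1, paste, collapse = ""),
             wt_peptide = apply(wt, 1, paste, collapse = ""),
             mut_pos = pos, ic50_mt = ic50_mt, ic50_wt = ic50_wt)
}

#' Simulate right-censored survival
#'
#' Event times are exponential with rate `h0 * exp(beta * x)`; censoring
#' times are uniform on `(0, censor_window)`; the observed time is the
#' minimum with an event indicator.
#'
#' @param x Per-patient scalar risk feature.
#' @param beta Log hazard per unit of `x`.
#' @param h0 Baseline hazard per day.
#' @param censor_window Upper censoring bound in days; `Inf` disables
#'   censoring.
#' @return Data frame `os_days`, `os_event`.
#' @export
simulate_survival <- function(x, beta, h0, censor_window = Inf) {
  rate <- h0 * exp(beta * x)
  t_event <- stats::rexp(length(x), rate)
  t_cens <- if (is.finite(censor_window)) {
    stats::runif(length(x), 0, censor_window)
  } else rep(Inf, length(x))
  data.frame(os_days = pmin(t_event, t_cens),
             os_event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic cohort
#'
#' Produces a full [neo_cohort()] with two planted survival groups plus the
#' planted truth. The long-term group's peptides are enriched for R/S at
#' positions 3-4 and its hazard is lower by `exp(beta)`; the short-term
#' group is enriched for L/G. A mutation table with Poisson missense loads
#' is included so the baseline stratifiers can run.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a `neo_cohort`) and `truth` (data frame
#'   `patient_id`, `group` (`"long"`/`"short"`), `risk`).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    group <- rep(c("long", "short"), length.out = n)
    npep <- pmax(1L, stats::rpois(n, config$lambda))
    pair_list <- lapply(seq_len(n), function(i) {
      enrich <- if (group[i] == "long") c("R", "S") else c("L", "G")
      generate_peptide_pairs(npep[i], ids[i], enrich = enrich,
                             bias = config$bias,
                             prop_pass = config$prop_pass)
    })
    pairs <- do.call(rbind, pair_list)
    risk <- ifelse(group == "short", 0.5, -0.5)
    surv <- simulate_survival(risk, config$beta, config$h0,
                              config$censor_window)
    clinical <- data.frame(patient_id = ids, os_days = surv$os_days,
                           os_event = surv$os_event,
                           age = round(stats::rnorm(n, 60, 10)))
    n_mut <- stats::rpois(n, 40)
    mutations <- data.frame(
      Tumor_Sample_Barcode = rep(ids, n_mut + 3L),
      Hugo_Symbol = "GENE",
      Variant_Classification = unlist(lapply(n_mut, function(k) {
        c(rep("Missense_Mutation", k), "Silent", "Nonsense_Mutation",
          "Frame_Shift_Del")
      })))
    cohort <- neo_cohort(clinical, pairs, mutations, name = "synthetic")
    list(cohort = cohort,
         truth = data.frame(patient_id = ids, group = group, risk = risk))
  })
}
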