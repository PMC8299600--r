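# Cohort data model and file I/O: peptide-pair, clinical and MAF-style
# mutation tables, neoantigen calling, DAI and mutational-load counts.

PAIR_COLS <- c("patient_id", "mt_peptide", "wt_peptide", "mut_pos",
               "ic50_mt", "ic50_wt")

#' Validate a peptide-pair table
#'
#' Checks the structural invariants of mutant/wild-type pair records: 9-mer
#' sequences over the standard alphabet, mutant and wild type differing at
#' exactly one position which equals `mut_pos`, and positive IC50 values.
#'
#' @param pairs Data frame with columns `patient_id`, `mt_peptide`,
#'   `wt_peptide`, `mut_pos`, `ic50_mt`, `ic50_wt`.
#' @return The validated data frame (invisibly unchanged apart from
#'   upper-cased sequences).
#' @export
validate_pairs <- function(pairs) {
  miss <- setdiff(setdiff(PAIR_COLS, c("ic50_mt", "ic50_wt")), names(pairs))
  if (length(miss)) stop("peptide table lacks columns: ",
                         paste(miss, collapse = ", "))
  pairs$mt_peptide <- toupper(as.character(pairs$mt_peptide))
  pairs$wt_peptide <- toupper(as.character(pairs$wt_peptide))
  mt <- .seq_matrix(pairs$mt_peptide, what = "mt_peptide")
  wt <- .seq_matrix(pairs$wt_peptide, what = "wt_peptide")
  ndiff <- rowSums(mt != wt)
  if (any(ndiff != 1L)) {
    stop("mt/wt must differ at exactly one position; offending rows: ",
         paste(utils::head(which(ndiff != 1L), 5L), collapse = ", "))
  }
  diffpos <- max.col(mt != wt)
  pos <- as.integer(pairs$mut_pos)
  if (any(is.na(pos)) || any(pos < 1L | pos > 9L) || any(pos != diffpos)) {
    stop("mut_pos must be the (1-based) position where mt and wt differ; ",
         "offending rows: ",
         paste(utils::head(which(is.na(pos) | pos != diffpos), 5L),
               collapse = ", "))
  }
  for (cc in c("ic50_mt", "ic50_wt")) {
    if (cc %in% names(pairs) &&
        any(!is.finite(pairs[[cc]]) | pairs[[cc]] <= 0)) {
      stop(cc, " must be positive and finite")
    }
  }
  pairs
}

#' Assemble a cohort
#'
#' Bundles clinical records, peptide pairs and (optionally) mutation records,
#' enforcing that every peptide-pair patient has a clinical record. Patients
#' with clinical data but no pairs are retained (they are excluded later, at
#' featurization).
#'
#' @param clinical Data frame with `patient_id`, `os_days`, `os_event` and
#'   optional covariate columns.
#' @param pairs Peptide-pair data frame (see [validate_pairs()]).
#' @param mutations Optional MAF-style data frame with
#'   `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`.
#' @param name Cohort label.
#' @return An object of class `neo_cohort`.
#' @export
neo_cohort <- function(clinical, pairs, mutations = NULL, name = "cohort") {
  need <- c("patient_id", "os_days", "os_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  clinical$patient_id <- as.character(clinical$patient_id)
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicate patient_id in clinical table")
  }
  if (any(!is.finite(clinical$os_days) | clinical$os_days < 0)) {
    stop("os_days must be finite and non-negative")
  }
  if (!all(clinical$os_event %in% c(0, 1))) {
    stop("os_event must be 0 (censored) or 1 (death)")
  }
  pairs <- validate_pairs(pairs)
  pairs$patient_id <- as.character(pairs$patient_id)
  orphan <- setdiff(unique(pairs$patient_id), clinical$patient_id)
  if (length(orphan)) {
    stop("peptide pairs for patients without clinical records: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  if (!is.null(mutations)) {
    mneed <- c("Tumor_Sample_Barcode", "Hugo_Symbol",
               "Variant_Classification")
    mmiss <- setdiff(mneed, names(mutations))
    if (length(mmiss)) stop("mutation table lacks columns: ",
                            paste(mmiss, collapse = ", "))
    mutations$Tumor_Sample_Barcode <-
      as.character(mutations$Tumor_Sample_Barcode)
  }
  structure(list(clinical = clinical, pairs = pairs, mutations = mutations,
                 name = name), class = "neo_cohort")
}

#' @export
print.neo_cohort <- function(x, ...) {
  cat("neo_cohort '", x$name, "': ", nrow(x$clinical), " patients, ",
      nrow(x$pairs), " peptide pairs",
      if (!is.null(x$mutations)) paste0(", ", nrow(x$mutations),
                                        " mutation records"),
      "\n", sep = "")
  invisible(x)
}

#' Read / write cohort tables
#'
#' Tab-delimited readers and writers for the three cohort tables. Writers and
#' readers round-trip exactly.
#'
#' @param path File path.
#' @return `read_peptides`/`read_clinical`/`read_mutations` return data
#'   frames; writers return the path invisibly.
#' @name cohort_tables
NULL

#' @rdname cohort_tables
#' @export
read_peptides <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = c(patient_id = "character"))
  validate_pairs(d)
}

#' @rdname cohort_tables
#' @param pairs,clinical,mutations Tables to write.
#' @export
write_peptides <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_tables
#' @export
read_clinical <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(patient_id = "character"))
}

#' @rdname cohort_tables
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_tables
#' @export
read_mutations <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = c(Tumor_Sample_Barcode = "character"))
}

#' @rdname cohort_tables
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Call neoantigens by the 500 nM rule
#'
#' Keeps pairs whose mutant peptide is a predicted binder and whose wild-type
#' counterpart is not: `ic50_mt < 500` and `ic50_wt > 500` nM, both strict.
#' Order-preserving and idempotent.
#'
#' @param pairs Peptide-pair data frame with IC50 columns.
#' @return The kept subset.
#' @export
call_neoantigens <- function(pairs) {
  if (!all(c("ic50_mt", "ic50_wt") %in% names(pairs))) {
    stop("calling requires ic50_mt and ic50_wt columns")
  }
  if (any(!is.finite(pairs$ic50_mt) | pairs$ic50_mt <= 0) ||
      any(!is.finite(pairs$ic50_wt) | pairs$ic50_wt <= 0)) {
    stop("IC50 values must be positive")
  }
  pairs[pairs$ic50_mt < 500 & pairs$ic50_wt > 500, , drop = FALSE]
}

#' Differential agretopicity index
#'
#' Per-pair DAI is the wild-type minus mutant binding affinity. On the
#' default nM scale `DAI = ic50_wt - ic50_mt`; with `scale = "log10"` the
#' difference of log10 affinities is used.
#'
#' @param pairs Called neoantigen pairs.
#' @param scale `"nM"` (default) or `"log10"`.
#' @return Numeric vector of per-pair DAI values.
#' @export
compute_dai <- function(pairs, scale = c("nM", "log10")) {
  scale <- match.arg(scale)
  if (scale == "nM") pairs$ic50_wt - pairs$ic50_mt
  else log10(pairs$ic50_wt) - log10(pairs$ic50_mt)
}

#' Per-patient mean DAI
#'
#' @param cohort A `neo_cohort` (pairs are filtered by [call_neoantigens()]
#'   first).
#' @inheritParams compute_dai
#' @return Named numeric vector over patients with at least one called pair.
#' @export
patient_mean_dai <- function(cohort, scale = c("nM", "log10")) {
  pairs <- call_neoantigens(cohort$pairs)
  if (nrow(pairs) == 0L) stop("no called neoantigens in cohort")
  dai <- compute_dai(pairs, scale)
  tapply(dai, pairs$patient_id, mean)
}

#' Per-patient missense mutational load
#'
#' Counts `Missense_Mutation` records per patient; patients present in the
#' clinical table but absent from the mutation table count 0.
#'
#' @param cohort A `neo_cohort` with a mutation table.
#' @return Named integer vector over all clinical patients.
#' @export
missense_load <- function(cohort) {
  if (is.null(cohort$mutations)) stop("cohort has no mutation table")
  mm <- cohort$mutations
  mm <- mm[mm$Variant_Classification == "Missense_Mutation", , drop = FALSE]
  tab <- table(factor(mm$Tumor_Sample_Barcode,
                      levels = cohort$clinical$patient_id))
  out <- as.integer(tab)
  names(out) <- cohort$clinical$patient_id
  out
}

#' Per-patient neoantigen count
#'
#' Number of called neoantigen pairs per patient; patients with none count 0.
#'
#' @param cohort A `neo_cohort`.
#' @return Named integer vector over all clinical patients.
#' @export
neoantigen_count <- function(cohort) {
  called <- call_neoantigens(cohort$pairs)
  tab <- table(factor(called$patient_id,
                      levels = cohort$clinical$patient_id))
  out <- as.integer(tab)
  names(out) <- cohort$clinical$patient_id
  out
}
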