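# Intrinsic-feature encoding of mutant/wild-type 9-mer pairs.
#
# Every feature is a (peptide role, sequence unit, measure) triple. Units are
# the nine absolute positions, the eight adjacent dipeptides, the seven
# adjacent tripeptides, the whole sequence, and mutation-anchored copies of
# the mutated position and the di-/tripeptides containing it. Measures are
# the 66 descriptor components, the nine class flags (single positions), the
# unit molecular weight (multi-residue units), and for the whole sequence the
# physico-chemical panel, class-composition fractions and Shannon entropy.

PHYSCHEM_NAMES <- c("AliphaticIndex", "BomanIndex", "Charge",
                    "HydrophobicMoment", "GRAVY", "Hydrophobicity",
                    "MW", "pI")

#' Shannon entropy of a 9-mer
#'
#' Residue-composition entropy in bits: \eqn{H = -\sum_a f_a \log_2 f_a} over
#' the frequencies of the residues present. Ranges from 0 (homopolymer) to
#' \eqn{\log_2 9} (all residues distinct).
#'
#' @param seq Character vector of 9-mer peptide strings (standard residues).
#' @return Numeric vector of entropies in bits.
#' @export
#' @examples
#' shannon_entropy("AAAAAAAAA")  # 0
#' shannon_entropy("ACDEFGHIK")  # log2(9)
shannon_entropy <- function(seq) {
  m <- .seq_matrix(seq)
  cnt <- .residue_counts(m)
  f <- cnt / ncol(m)
  h <- -rowSums(ifelse(f > 0, f * log2(f), 0))
  unname(h)
}

# n x 20 residue count matrix from an n x w residue matrix.
.residue_counts <- function(m) {
  n <- nrow(m)
  cnt <- matrix(0, n, 20L, dimnames = list(NULL, AA20))
  for (j in seq_len(ncol(m))) {
    idx <- cbind(seq_len(n), match(m[, j], AA20))
    cnt[idx] <- cnt[idx] + 1
  }
  cnt
}

#' Descriptor value of a 1-3 residue unit
#'
#' Single residues are table lookups; multi-residue units take the arithmetic
#' mean of the constituent residues' values.
#'
#' @param residues String of 1-3 standard residues (vectorized).
#' @param component Descriptor component id, e.g. `"KF1"`, `"VHSE6"`, `"ST4"`.
#' @return Numeric vector of descriptor values.
#' @export
unit_descriptor <- function(residues, component) {
  D <- aa_descriptors()
  bad <- setdiff(component, colnames(D))
  if (length(bad)) {
    stop("unknown descriptor component: ", paste(bad, collapse = ", "))
  }
  k <- max(length(residues), length(component))
  residues <- rep_len(toupper(residues), k)
  component <- rep_len(component, k)
  vapply(seq_len(k), function(i) {
    ch <- strsplit(residues[i], "")[[1]]
    if (!length(ch) %in% 1:3 || !all(ch %in% AA20)) {
      stop("unit must be 1-3 standard residues, got: ", residues[i])
    }
    mean(D[ch, component[i]])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Molecular weight of a residue unit
#'
#' Sum of average residue masses plus one water (18.02 Da), i.e. the mass of
#' the free peptide formed by the unit.
#'
#' @param residues String(s) of standard residues.
#' @return Mass in daltons.
#' @export
#' @examples
#' unit_molecular_weight("G")   # ~75.07
#' unit_molecular_weight("GG")  # ~132.12
unit_molecular_weight <- function(residues) {
  vapply(toupper(residues), function(r) {
    ch <- strsplit(r, "")[[1]]
    if (!all(ch %in% AA20)) stop("non-standard residue in: ", r)
    sum(AA_MASS[ch]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Class flags of a residue
#'
#' Binary membership in the nine composition classes.
#'
#' @param residue Single-letter residue code (vectorized).
#' @return Matrix with one row per input and the nine class columns.
#' @export
aa_class_flags <- function(residue) {
  C <- aa_classes()
  residue <- toupper(residue)
  if (!all(residue %in% AA20)) {
    stop("non-standard residue: ",
         paste(setdiff(residue, AA20), collapse = ", "))
  }
  C[residue, , drop = FALSE]
}

#' Physico-chemical property panel of a 9-mer
#'
#' Computes the eight whole-sequence properties used in featurization:
#' aliphatic index, Boman index, net charge at pH 7 (EMBOSS pKa set),
#' Eisenberg hydrophobic moment (alpha-helical 100 degree periodicity), GRAVY
#' (Kyte-Doolittle), mean Eisenberg hydrophobicity, molecular weight, and
#' isoelectric point.
#'
#' @param seq Character vector of 9-mers.
#' @return Numeric matrix, one row per peptide, one column per property.
#' @export
physchem_properties <- function(seq) {
  m <- .seq_matrix(seq)
  .physchem_from_matrix(m)
}

.net_charge <- function(cnt, pH) {
  pos <- 1 / (1 + 10^(pH - PKA_POS["Nterm"])) +
    cnt[, "K"] / (1 + 10^(pH - PKA_POS["K"])) +
    cnt[, "R"] / (1 + 10^(pH - PKA_POS["R"])) +
    cnt[, "H"] / (1 + 10^(pH - PKA_POS["H"]))
  neg <- 1 / (1 + 10^(PKA_NEG["Cterm"] - pH)) +
    cnt[, "D"] / (1 + 10^(PKA_NEG["D"] - pH)) +
    cnt[, "E"] / (1 + 10^(PKA_NEG["E"] - pH)) +
    cnt[, "C"] / (1 + 10^(PKA_NEG["C"] - pH)) +
    cnt[, "Y"] / (1 + 10^(PKA_NEG["Y"] - pH))
  unname(pos - neg)
}

.isoelectric_point <- function(cnt) {
  lo <- rep(0, nrow(cnt))
  hi <- rep(14, nrow(cnt))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    q <- .net_charge(cnt, mid)
    up <- q > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

.physchem_from_matrix <- function(m) {
  n <- nrow(m)
  w <- ncol(m)
  cnt <- .residue_counts(m)
  f <- cnt / w
  ai <- 100 * (f[, "A"] + 2.9 * f[, "V"] + 3.9 * (f[, "I"] + f[, "L"]))
  boman <- -as.vector(cnt %*% AA_BOMAN) / w
  charge <- .net_charge(cnt, 7)
  h <- matrix(AA_EISENBERG[m], n, w)
  ang <- (seq_len(w) - 1) * 100 * pi / 180
  mu <- sqrt(as.vector(h %*% cos(ang))^2 + as.vector(h %*% sin(ang))^2) / w
  gravy <- as.vector(cnt %*% AA_KD) / w
  hyd <- as.vector(cnt %*% AA_EISENBERG) / w
  mw <- as.vector(cnt %*% AA_MASS) + WATER_MASS
  pi_ <- .isoelectric_point(cnt)
  out <- cbind(AliphaticIndex = ai, BomanIndex = boman, Charge = charge,
               HydrophobicMoment = mu, GRAVY = gravy, Hydrophobicity = hyd,
               MW = mw, pI = pi_)
  rownames(out) <- NULL
  out
}

#' The intrinsic-feature vocabulary
#'
#' Deterministic, ordered list of feature names for one or both peptide roles.
#' Names follow `"{MT|WT}.peptide.{unit}.{measure}"` where unit is a position
#' (`"4"`), a span (`"3-4"`), `"full"`, or a mutation-anchored unit (`"mut"`,
#' `"mutdi1"`, `"mutdi2"`, `"muttri1"`-`"muttri3"`).
#'
#' @param roles Peptide roles to include, default both `"MT"` and `"WT"`.
#' @return Character vector of feature names; the computation plan backing it
#'   is attached as attribute `"plan"`.
#' @export
feature_vocabulary <- function(roles = c("MT", "WT")) {
  roles <- match.arg(roles, c("MT", "WT"), several.ok = TRUE)
  desc <- colnames(aa_descriptors())
  cls <- colnames(aa_classes())
  plan <- list()
  for (role in roles) {
    for (p in 1:9) {
      plan[[length(plan) + 1L]] <- data.frame(
        role = role, unit = "pos", start = p,
        measure = c(desc, cls), span = as.character(p))
    }
    for (p in 1:8) {
      plan[[length(plan) + 1L]] <- data.frame(
        role = role, unit = "di", start = p,
        measure = c(desc, "MW"), span = paste0(p, "-", p + 1))
    }
    for (p in 1:7) {
      plan[[length(plan) + 1L]] <- data.frame(
        role = role, unit = "tri", start = p,
        measure = c(desc, "MW"), span = paste0(p, "-", p + 2))
    }
    plan[[length(plan) + 1L]] <- data.frame(
      role = role, unit = "full", start = NA_integer_,
      measure = c(desc, PHYSCHEM_NAMES, paste0("frac.", cls), "Entropy"),
      span = "full")
    plan[[length(plan) + 1L]] <- data.frame(
      role = role, unit = "mut", start = NA_integer_,
      measure = c(desc, cls), span = "mut")
    for (k in 1:2) {
      plan[[length(plan) + 1L]] <- data.frame(
        role = role, unit = paste0("mutdi", k), start = NA_integer_,
        measure = c(desc, "MW"), span = paste0("mutdi", k))
    }
    for (k in 1:3) {
      plan[[length(plan) + 1L]] <- data.frame(
        role = role, unit = paste0("muttri", k), start = NA_integer_,
        measure = c(desc, "MW"), span = paste0("muttri", k))
    }
  }
  plan <- do.call(rbind, plan)
  nm <- paste(plan$role, "peptide", plan$span, plan$measure, sep = ".")
  stopifnot(!anyDuplicated(nm))
  structure(nm, plan = plan)
}

# Values of one unit block for all pairs: returns n x length(measures) matrix.
# sidx: n x 9 matrix of residue indices into AA20; pos: unit start per row
# (may contain NA for invalid mutation-anchored units).
.unit_block <- function(sidx, pos, width, measures) {
  D <- aa_descriptors()
  C <- aa_classes()
  n <- nrow(sidx)
  out <- matrix(NA_real_, n, length(measures),
                dimnames = list(NULL, measures))
  ok <- !is.na(pos) & pos >= 1L & pos + width - 1L <= 9L
  if (!any(ok)) return(out)
  rows <- which(ok)
  acc <- matrix(0, length(rows), 66L)
  mass <- numeric(length(rows))
  for (off in 0:(width - 1L)) {
    ri <- sidx[cbind(rows, pos[rows] + off)]
    acc <- acc + D[ri, , drop = FALSE]
    mass <- mass + AA_MASS[ri]
  }
  desc_cols <- colnames(D)[colnames(D) %in% measures]
  out[rows, desc_cols] <- (acc / width)[, desc_cols]
  if ("MW" %in% measures) out[rows, "MW"] <- mass + WATER_MASS
  flag_cols <- colnames(C)[colnames(C) %in% measures]
  if (length(flag_cols) && width == 1L) {
    ri <- sidx[cbind(rows, pos[rows])]
    out[rows, flag_cols] <- C[ri, flag_cols, drop = FALSE]
  }
  out
}

#' Featurize mutant/wild-type peptide pairs
#'
#' Computes the full intrinsic-feature vector for every peptide pair.
#' Mutation-anchored units that fall outside positions 1-9 are `NA` (masked);
#' all other values are finite.
#'
#' @param pairs Data frame with columns `patient_id`, `mt_peptide`,
#'   `wt_peptide`, `mut_pos`, and optionally `ic50_mt`, `ic50_wt`.
#' @param vocab Feature vocabulary from [feature_vocabulary()].
#' @return Numeric matrix, one row per pair, columns in vocabulary order, with
#'   the per-row patient ids in attribute `"patient_id"`.
#' @export
featurize_pairs <- function(pairs, vocab = feature_vocabulary()) {
  pairs <- validate_pairs(pairs)
  plan <- attr(vocab, "plan")
  n <- nrow(pairs)
  mt <- .seq_matrix(pairs$mt_peptide, what = "mt_peptide")
  wt <- .seq_matrix(pairs$wt_peptide, what = "wt_peptide")
  sidx <- list(MT = matrix(match(mt, AA20), n, 9L),
               WT = matrix(match(wt, AA20), n, 9L))
  smat <- list(MT = mt, WT = wt)
  mpos <- as.integer(pairs$mut_pos)
  out <- matrix(NA_real_, n, length(vocab), dimnames = list(NULL, vocab))
  key <- paste(plan$role, plan$unit, plan$start)
  for (g in unique(key)) {
    sel <- key == g
    role <- plan$role[sel][1L]
    unit <- plan$unit[sel][1L]
    start <- plan$start[sel][1L]
    measures <- plan$measure[sel]
    si <- sidx[[role]]
    block <- switch(
      unit,
      pos = .unit_block(si, rep(start, n), 1L, measures),
      di = .unit_block(si, rep(start, n), 2L, measures),
      tri = .unit_block(si, rep(start, n), 3L, measures),
      mut = .unit_block(si, mpos, 1L, measures),
      mutdi1 = .unit_block(si, mpos - 1L, 2L, measures),
      mutdi2 = .unit_block(si, mpos, 2L, measures),
      muttri1 = .unit_block(si, mpos - 2L, 3L, measures),
      muttri2 = .unit_block(si, mpos - 1L, 3L, measures),
      muttri3 = .unit_block(si, mpos, 3L, measures),
      full = .full_block(smat[[role]], si, measures)
    )
    out[, sel] <- block
  }
  attr(out, "patient_id") <- as.character(pairs$patient_id)
  out
}

.full_block <- function(m, si, measures) {
  D <- aa_descriptors()
  C <- aa_classes()
  n <- nrow(m)
  acc <- matrix(0, n, 66L, dimnames = list(NULL, colnames(D)))
  for (j in 1:9) acc <- acc + D[si[, j], , drop = FALSE]
  desc_mean <- acc / 9
  pc <- .physchem_from_matrix(m)
  cnt <- .residue_counts(m)
  fr <- (cnt %*% C) / 9
  colnames(fr) <- paste0("frac.", colnames(C))
  ent <- {
    f <- cnt / 9
    -rowSums(ifelse(f > 0, f * log2(f), 0))
  }
  all <- cbind(desc_mean, pc, fr, Entropy = ent)
  all[, measures, drop = FALSE]
}

#' Aggregate per-pair features to patients
#'
#' Element-wise mean over each patient's pairs, ignoring masked (`NA`)
#' entries; an entry stays `NA` only when masked in every pair.
#'
#' @param features Matrix from [featurize_pairs()] (carries patient ids) or
#'   any numeric matrix.
#' @param patient_id Patient id per row; defaults to the attribute set by
#'   [featurize_pairs()].
#' @return Numeric matrix with one row per patient (rownames = patient id).
#' @export
aggregate_patients <- function(features,
                               patient_id = attr(features, "patient_id")) {
  if (is.null(patient_id)) stop("patient_id is required")
  if (nrow(features) == 0L) stop("no feature rows to aggregate")
  stopifnot(length(patient_id) == nrow(features))
  obs <- !is.na(features)
  vals <- features
  vals[!obs] <- 0
  s <- rowsum(vals, patient_id)
  k <- rowsum(obs + 0, patient_id)
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Position-specific residue frequency matrix
#'
#' Occurrence frequency of each residue at each of the nine positions over a
#' set of peptide pairs, for the mutant or wild-type role (the data behind
#' sequence logos).
#'
#' @param pairs Peptide-pair data frame.
#' @param role `"MT"` or `"WT"`.
#' @return 20 x 9 matrix (residues x positions); columns sum to 1.
#' @export
residue_frequency_matrix <- function(pairs, role = c("MT", "WT")) {
  role <- match.arg(role)
  seqs <- if (role == "MT") pairs$mt_peptide else pairs$wt_peptide
  if (length(seqs) == 0L) stop("no peptide pairs")
  m <- .seq_matrix(seqs)
  out <- vapply(1:9, function(p) {
    tab <- table(factor(m[, p], levels = AA20))
    as.numeric(tab) / nrow(m)
  }, numeric(20L))
  dimnames(out) <- list(AA20, paste0("pos", 1:9))
  out
}

#' Resolve a free-form feature label to a vocabulary name
#'
#' Maps labels in the loose style used in figures and running text (for
#' example `"Mutated peptide 4 Aliphatic"`, `"MT.peptide 4 VHSE6"`,
#' `"Mutated peptide 3-4 ST4"`) onto the canonical
#' `"{role}.peptide.{unit}.{measure}"` vocabulary names.
#'
#' @param labels Character vector of labels.
#' @param vocab Vocabulary to resolve against.
#' @return Character vector of canonical names (error if unresolvable).
#' @export
resolve_feature_name <- function(labels, vocab = feature_vocabulary()) {
  alias <- c(
    "non.polar" = "NonPolar", "nonpolar" = "NonPolar", "polar" = "Polar",
    "basic" = "Basic", "acidic" = "Acidic", "aliphatic" = "Aliphatic",
    "aromatic" = "Aromatic", "tiny" = "Tiny", "small" = "Small",
    "charged" = "Charged", "mw" = "MW", "molecular.weight" = "MW")
  out <- vapply(labels, function(lab) {
    x <- gsub("–|—", "-", lab)
    x <- gsub("^(Mutated|Mutant)[ .]pep(tide)?", "MT.peptide", x,
              ignore.case = TRUE)
    x <- gsub("^(Wild[- ]?type|WT)[ .]pep(tide)?", "WT.peptide", x,
              ignore.case = TRUE)
    x <- gsub("[ ]+", ".", trimws(x))
    parts <- strsplit(x, "\\.")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 4L) stop("cannot parse feature label: ", lab)
    measure <- paste(parts[4:length(parts)], collapse = ".")
    key <- tolower(measure)
    if (key %in% names(alias)) measure <- alias[[key]]
    measure <- sub("^MESHIM", "MSWHIM", measure, ignore.case = TRUE)
    measure <- sub("^MS-?WHIM", "MSWHIM", measure, ignore.case = TRUE)
    measure <- sub("^protFP", "ProtFP", measure)
    measure <- sub("^ST-?scales?", "ST", measure, ignore.case = TRUE)
    measure <- sub("^T-?scales?", "T", measure)
    measure <- sub("^VHSE-?scales?", "VHSE", measure, ignore.case = TRUE)
    measure <- sub("^Z-?scales?", "Z", measure, ignore.case = TRUE)
    nm <- paste(parts[1], "peptide", parts[3], measure, sep = ".")
    if (!nm %in% vocab) stop("label does not resolve to a feature: ", lab,
                             " -> ", nm)
    nm
  }, character(1), USE.NAMES = FALSE)
  out
}
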