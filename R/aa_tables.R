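# Amino-acid reference data: descriptor scales, class membership, residue-level
# physico-chemical constants. Descriptor and class tables ship as plain TSV in
# inst/extdata so they can be inspected or replaced without touching code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average residue masses (Da); peptide MW = sum + one water.
AA_MASS <- c(
  A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.0153

# Kyte-Doolittle hydropathy (GRAVY).
AA_KD <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Eisenberg consensus hydrophobicity; also drives the hydrophobic moment.
AA_EISENBERG <- c(
  A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48, H = -0.40,
  I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78, P = 0.12, Q = -0.85,
  R = -2.53, S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)

# Water-cyclohexane transfer free energies (kcal/mol) behind the Boman index;
# index = -mean, so hydrophilic (protein-binding prone) peptides score high.
AA_BOMAN <- c(
  A = 1.81, C = 1.28, D = -8.72, E = -6.81, F = 2.98, G = 0.94, H = -4.66,
  I = 4.92, K = -5.55, L = 4.92, M = 2.35, N = -6.64, P = 0.00, Q = -5.54,
  R = -14.92, S = -3.40, T = -2.57, V = 4.04, W = 2.33, Y = -0.14)

# EMBOSS pKa set for charge / isoelectric point.
PKA_POS <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEG <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

.neodl_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "neodl")
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}

#' Amino-acid descriptor table
#'
#' The 66 descriptor components used for featurization: Cruciani properties
#' (PP1-3), Kidera factors (KF1-10), Z-scales (Z1-5), FASGAI factors (F1-6),
#' T-scales (T1-5), VHSE (VHSE1-8), ProtFP (ProtFP1-8), ST-scales (ST1-8),
#' BLOSUM indices (BLOSUM1-10) and MS-WHIM (MSWHIM1-3), transcribed from the
#' original publications and bundled as a plain TSV.
#'
#' @return A 20 x 66 numeric matrix, rows named by one-letter residue code,
#'   columns by descriptor component.
#' @export
#' @examples
#' aa_descriptors()["A", "KF4"]
aa_descriptors <- function() {
  if (is.null(.neodl_cache$desc)) {
    d <- utils::read.delim(.extdata("aa_descriptors.tsv"), check.names = FALSE)
    m <- as.matrix(d[, -1])
    rownames(m) <- d$residue
    stopifnot(identical(sort(rownames(m)), sort(AA20)), ncol(m) == 66L)
    .neodl_cache$desc <- m[AA20, ]
  }
  .neodl_cache$desc
}

#' Amino-acid class membership table
#'
#' Binary membership of each standard residue in the nine composition classes
#' (Tiny, Small, Aliphatic, Aromatic, NonPolar, Polar, Charged, Basic, Acidic).
#'
#' @return A 20 x 9 binary matrix (rows residues, columns classes).
#' @export
aa_classes <- function() {
  if (is.null(.neodl_cache$cls)) {
    d <- utils::read.delim(.extdata("aa_classes.tsv"), check.names = FALSE)
    m <- as.matrix(d[, -1])
    rownames(m) <- d$residue
    storage.mode(m) <- "double"
    .neodl_cache$cls <- m[AA20, ]
  }
  .neodl_cache$cls
}

# Validate peptide strings: standard residues only. Returns matrix of residues.
.seq_matrix <- function(seqs, width = 9L, what = "peptide") {
  seqs <- toupper(as.character(seqs))
  bad <- nchar(seqs) != width
  if (any(bad)) {
    stop(what, " must be ", width, "-mers; offending rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              ncol = width, byrow = TRUE)
  nonstd <- !(m %in% AA20)
  if (any(nonstd)) {
    rows <- unique(which(matrix(nonstd, ncol = width), arr.ind = TRUE)[, 1L])
    stop("non-standard residues (only the 20 standard amino acids are ",
         "supported) in ", what, " rows: ",
         paste(utils::head(rows, 5L), collapse = ", "))
  }
  m
}
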