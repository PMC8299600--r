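# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except the package's own bundled tables.

# A handful of hand-written valid pairs (one substitution, position matches).
toy_pairs <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2", "P3"),
    mt_peptide = c("ACDEFGHIK", "LLLLVLLLL", "RSTRSTRST", "GGGGGGGGW"),
    wt_peptide = c("ACDEFGHIR", "LLLLLLLLL", "RSTRSTRSA", "GGGGGGGGG"),
    mut_pos = c(9L, 5L, 9L, 9L),
    ic50_mt = c(100, 300, 450, 20),
    ic50_wt = c(900, 501, 5000, 499),
    stringsAsFactors = FALSE)
}

toy_clinical <- function() {
  data.frame(patient_id = c("P1", "P2", "P3"),
             os_days = c(120, 600, 350), os_event = c(1L, 0L, 1L),
             stringsAsFactors = FALSE)
}

# Small training-ready matrix with a mean-shift group structure.
shifted_matrix <- function(n = 60, p = 12, delta = 3, seed = 1) {
  neodl:::with_seed(seed, {
    g <- rep(0:1, length.out = n)
    x <- matrix(rnorm(n * p), n, p) + delta * g
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, g = g)
  })
}

# Tiny model configuration used wherever the test property does not depend
# on network width or long training.
tiny_config <- function(...) {
  args <- list(hidden = c(8L, 6L, 4L), epochs = 30L, batch_size = 16L,
               seed = 42L)
  over <- list(...)
  args[names(over)] <- over
  do.call(neodl_config, args)
}
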