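# Featurization: entropy, descriptor units, class flags, physico-chemical
# panel, vocabulary structure and the pair-level feature vectors.

test_that("shannon entropy matches closed forms and bounds", {
  expect_equal(shannon_entropy("AAAAAAAAA"), 0)
  expect_equal(shannon_entropy("ACDEFGHIK"), log2(9), tolerance = 1e-12)
  # two-symbol composition 5/9, 4/9
  h <- -(5 / 9) * log2(5 / 9) - (4 / 9) * log2(4 / 9)
  expect_equal(shannon_entropy("AAAAACCCC"), h, tolerance = 1e-12)
  # bounds and homopolymer characterization over random sequences
  set.seed(11)
  seqs <- replicate(50, paste(sample(neodl:::AA20, 9, TRUE), collapse = ""))
  hs <- shannon_entropy(seqs)
  expect_true(all(hs >= 0 & hs <= log2(9) + 1e-12))
  expect_error(shannon_entropy("AAAAAAAAX"), "non-standard")
})

test_that("unit descriptors are residue-mean lookups", {
  # independently re-typed reference rows (Kidera A, R; Z-scales A)
  expect_equal(unname(unit_descriptor("A", paste0("KF", 1:10))),
               c(-1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,
                 0.21, -0.48))
  expect_equal(unname(unit_descriptor("R", paste0("KF", 1:10))),
               c(0.22, 1.27, 1.37, 1.87, -1.70, 0.46, 0.92, -0.39, 0.23,
                 0.93))
  expect_equal(unname(unit_descriptor("A", paste0("Z", 1:5))),
               c(0.24, -2.32, 0.60, -0.14, 1.30))
  # mean rule
  expect_equal(unit_descriptor("AA", "VHSE6"), unit_descriptor("A", "VHSE6"))
  expect_equal(unit_descriptor("AC", "ST4"),
               (unit_descriptor("A", "ST4") + unit_descriptor("C", "ST4")) / 2)
  expect_error(unit_descriptor("A", "NOPE7"), "unknown")
})

test_that("descriptor table has the pinned structure", {
  D <- aa_descriptors()
  expect_identical(dim(D), c(20L, 66L))
  fams <- c(PP = 3, KF = 10, Z = 5, F = 6, T = 5, VHSE = 8, ProtFP = 8,
            ST = 8, BLOSUM = 10, MSWHIM = 3)
  expect_identical(colnames(D),
                   unlist(lapply(names(fams), function(f)
                     paste0(f, seq_len(fams[[f]]))), use.names = FALSE))
  expect_false(anyNA(D))
})

test_that("unit molecular weight is mass sum plus one water", {
  expect_equal(unit_molecular_weight("G"), 75.07, tolerance = 1e-3)
  expect_equal(unit_molecular_weight("GG"), 132.12, tolerance = 1e-3)
  # appending residues strictly increases the mass
  w1 <- unit_molecular_weight("AC")
  expect_true(unit_molecular_weight("ACG") > w1)
})

test_that("class flags follow the pinned membership table", {
  fa <- aa_class_flags("A")[1, ]
  expect_equal(fa[c("Tiny", "Small", "Aliphatic", "NonPolar")],
               c(Tiny = 1, Small = 1, Aliphatic = 1, NonPolar = 1))
  expect_equal(sum(fa), 4)
  fr <- aa_class_flags("R")[1, ]
  expect_equal(fr[c("Polar", "Charged", "Basic")],
               c(Polar = 1, Charged = 1, Basic = 1))
  expect_equal(sum(fr), 3)
  # aliphatic and aromatic are disjoint
  C <- aa_classes()
  expect_true(all(C[, "Aliphatic"] + C[, "Aromatic"] <= 1))
})

test_that("physico-chemical panel behaves as expected", {
  pc <- physchem_properties(c("KKKKKKKKK", "DDDDDDDDD", "IIIIIIIII",
                              "RRRRRRRRR"))
  expect_true(pc[1, "Charge"] > 0)
  expect_true(pc[2, "Charge"] < 0)
  expect_true(pc[3, "GRAVY"] > pc[4, "GRAVY"])
  # MW agrees with the unit definition on the full 9-mer
  expect_equal(pc[3, "MW"], unit_molecular_weight("IIIIIIIII"),
               tolerance = 1e-9, ignore_attr = TRUE)
  # pI brackets: polylysine basic, polyaspartate acidic
  expect_true(pc[1, "pI"] > 9)
  expect_true(pc[2, "pI"] < 5)
})

test_that("vocabulary is deterministic with the documented block structure", {
  v1 <- feature_vocabulary()
  v2 <- feature_vocabulary()
  expect_identical(as.character(v1), as.character(v2))
  expect_false(anyDuplicated(v1) > 0)
  # exact count: per role 9*(66+9) + 8*67 + 7*67 + (66+8+9+1) + (66+9)
  # + 2*67 + 3*67
  per_role <- 9 * 75 + 8 * 67 + 7 * 67 + 84 + 75 + 2 * 67 + 3 * 67
  expect_length(v1, 2 * per_role)
  expect_length(feature_vocabulary("MT"), per_role)
})

test_that("reported feature labels resolve into the vocabulary", {
  labels <- c("Mutated peptide 4 Aliphatic", "Mutated peptide 3-4 ST4",
              "MT.peptide 4 VHSE6", "MT.peptide 4 PP1",
              "Mutated peptide 5 basic", "Mutated peptide 7 VHSE6",
              "Mutated peptide 4 Non.polar",
              # the 12 protective features
              "MT.peptide 3-4 MW", "MT.peptide 3-4 KF2",
              "MT.peptide 3-4 Z2", "MT.peptide 3-4 T1",
              "MT.peptide 3-4 ProtFP2", "MT.peptide 3-4 VHSE2",
              "MT.peptide 3-4 VHSE3", "MT.peptide 3-4 VHSE6",
              "MT.peptide 3-4 ST1", "MT.peptide 2-4 BLOSUM2",
              "MT.peptide 2-4 MESHIM1")
  resolved <- resolve_feature_name(labels)
  expect_true(all(resolved %in% feature_vocabulary()))
  expect_identical(resolved[1], "MT.peptide.4.Aliphatic")
  expect_identical(resolved[length(labels)], "MT.peptide.2-4.MSWHIM1")
})

test_that("featurization is deterministic, symmetric and local", {
  pairs <- toy_pairs()
  f1 <- featurize_pairs(pairs)
  f2 <- featurize_pairs(pairs)
  expect_identical(f1, f2)
  v <- feature_vocabulary()
  plan <- attr(v, "plan")
  # role symmetry: swapping mt and wt swaps the MT- and WT-role blocks
  swapped <- pairs
  swapped$mt_peptide <- pairs$wt_peptide
  swapped$wt_peptide <- pairs$mt_peptide
  fs <- featurize_pairs(swapped)
  mt_block <- v[plan$role == "MT"]
  wt_block <- sub("^MT", "WT", mt_block)
  expect_equal(unname(f1[, mt_block]), unname(fs[, wt_block]))
  # pair differing only at position 9: positional features 1..8 equal
  p9 <- pairs[1, ]  # differs at 9
  f <- featurize_pairs(p9)
  pos <- plan$unit == "pos" & plan$start <= 8
  mt_cols <- v[pos & plan$role == "MT"]
  wt_cols <- sub("^MT", "WT", mt_cols)
  expect_equal(unname(f[1, mt_cols]), unname(f[1, wt_cols]))
  # whole-sequence MT vs WT differ (mutation is R->K at position 9)
  expect_false(isTRUE(all.equal(f[1, "MT.peptide.full.MW"],
                                f[1, "WT.peptide.full.MW"])))
})

test_that("mutation-anchored masking follows the window rule", {
  pairs <- toy_pairs()
  f <- featurize_pairs(pairs)
  # row 2 mutates position 5: all anchored units are in range
  expect_false(anyNA(f[2, ]))
  # row 1 mutates position 9: right-extending windows are masked
  expect_true(is.na(f[1, "MT.peptide.mutdi2.MW"]))
  expect_true(is.na(f[1, "MT.peptide.muttri3.MW"]))
  expect_false(is.na(f[1, "MT.peptide.mutdi1.MW"]))
  expect_false(is.na(f[1, "MT.peptide.mut.KF1"]))
})

test_that("patient aggregation averages over unmasked entries", {
  x <- matrix(c(1, 2, 3,
                3, NA, 5,
                10, 20, NA), 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  ag <- aggregate_patients(x, c("p1", "p1", "p2"))
  expect_equal(ag["p1", ], c(a = 2, b = 2, c = 4))
  expect_equal(ag["p2", "c"], NA_real_, ignore_attr = TRUE)
  # single vector is returned unchanged; order invariance
  expect_equal(aggregate_patients(x[3, , drop = FALSE], "p2")[1, ],
               x[3, ], ignore_attr = TRUE)
  perm <- c(2, 3, 1)
  ag2 <- aggregate_patients(x[perm, ], c("p1", "p2", "p1"))
  expect_equal(ag, ag2)
})

test_that("residue frequency matrix is column-normalized", {
  pairs <- toy_pairs()
  fm <- residue_frequency_matrix(pairs, "MT")
  expect_identical(dim(fm), c(20L, 9L))
  expect_equal(unname(colSums(fm)), rep(1, 9))
  # degenerate case: one shared sequence puts unit mass per position
  one <- pairs[rep(1, 5), ]
  fm1 <- residue_frequency_matrix(one, "MT")
  expect_true(all(apply(fm1, 2, max) == 1))
  # large uniform sample concentrates around 1/20 (3 sigma binomial bound)
  set.seed(3)
  n <- 4000
  seqs <- replicate(n, paste(sample(neodl:::AA20, 9, TRUE), collapse = ""))
  fake <- data.frame(patient_id = "p", mt_peptide = seqs, wt_peptide = seqs,
                     mut_pos = 1L)
  fmU <- residue_frequency_matrix(fake, "MT")
  bound <- 3 * sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(fmU - 0.05) < bound + 0.005))
})
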