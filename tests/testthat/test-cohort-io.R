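# Cohort model, readers/writers, neoantigen calling, DAI and load counts.

test_that("neoantigen calling applies the strict 500 nM rule", {
  p <- data.frame(patient_id = "p", mt_peptide = "ACDEFGHIK",
                  wt_peptide = "ACDEFGHIR", mut_pos = 9L,
                  ic50_mt = c(300, 500, 300, 499.9, 1),
                  ic50_wt = c(800, 800, 400, 500, 500.1))
  kept <- call_neoantigens(p)
  expect_identical(rownames(kept), c("1", "5"))
  # brute-force agreement on a random 100-row fixture
  set.seed(21)
  p2 <- p[rep(1, 100), ]
  p2$ic50_mt <- exp(runif(100, log(10), log(5000)))
  p2$ic50_wt <- exp(runif(100, log(10), log(5000)))
  kept2 <- call_neoantigens(p2)
  manual <- p2[p2$ic50_mt < 500 & p2$ic50_wt > 500, ]
  expect_identical(kept2, manual)
  # idempotent and order-preserving
  expect_identical(call_neoantigens(kept2), kept2)
  p2$ic50_mt[1] <- -1
  expect_error(call_neoantigens(p2), "positive")
})

test_that("DAI is the wild-type minus mutant affinity", {
  p <- toy_pairs()
  expect_equal(compute_dai(p), p$ic50_wt - p$ic50_mt)
  expect_equal(compute_dai(data.frame(ic50_wt = 501, ic50_mt = 499)), 2)
  # patient mean over called pairs
  pairs <- data.frame(patient_id = "p1",
                      mt_peptide = c("ACDEFGHIK", "ACDEFGHIK"),
                      wt_peptide = c("ACDEFGHIR", "ACDEFGHIR"),
                      mut_pos = 9L, ic50_mt = c(300, 499),
                      ic50_wt = c(800, 501))
  ch <- neo_cohort(data.frame(patient_id = "p1", os_days = 100,
                              os_event = 1L), pairs)
  expect_equal(unname(patient_mean_dai(ch)["p1"]), mean(c(500, 2)))
  # log scale option
  expect_equal(compute_dai(data.frame(ic50_wt = 1000, ic50_mt = 10),
                           scale = "log10"), 2)
})

test_that("missense load and neoantigen count handle absent patients", {
  clin <- data.frame(patient_id = c("p1", "p2", "p3"),
                     os_days = c(100, 200, 300), os_event = c(1L, 1L, 0L))
  pairs <- toy_pairs()
  pairs$patient_id <- c("p1", "p1", "p2", "p2")
  muts <- data.frame(
    Tumor_Sample_Barcode = c(rep("p1", 5), rep("p2", 2)),
    Hugo_Symbol = "G",
    Variant_Classification = c(rep("Missense_Mutation", 3), "Nonsense",
                               "Silent", "Missense_Mutation", "Silent"))
  ch <- neo_cohort(clin, pairs, muts)
  expect_equal(missense_load(ch), c(p1 = 3L, p2 = 1L, p3 = 0L))
  # brute-force scan agreement on a random 100-record fixture
  set.seed(5)
  big <- data.frame(
    Tumor_Sample_Barcode = sample(c("p1", "p2", "p3"), 100, TRUE),
    Hugo_Symbol = "G",
    Variant_Classification = sample(c("Missense_Mutation", "Silent",
                                      "Nonsense_Mutation"), 100, TRUE))
  ch2 <- neo_cohort(clin, pairs, big)
  manual <- vapply(clin$patient_id, function(p) {
    sum(big$Tumor_Sample_Barcode == p &
          big$Variant_Classification == "Missense_Mutation")
  }, integer(1))
  expect_equal(missense_load(ch2), manual)
  # neoantigen counts: only called pairs count, absent patients get 0
  nc <- neoantigen_count(ch)
  expect_equal(nc[["p3"]], 0L)
  expect_equal(unname(nc["p1"]),
               sum(call_neoantigens(pairs)$patient_id == "p1"))
})

test_that("cohort validation is loud about inconsistencies", {
  clin <- toy_clinical()
  pairs <- toy_pairs()
  expect_s3_class(neo_cohort(clin, pairs), "neo_cohort")
  # orphan peptide patient
  pairs2 <- pairs
  pairs2$patient_id[1] <- "P9"
  expect_error(neo_cohort(clin, pairs2), "without clinical")
  # bad survival fields
  clin2 <- clin; clin2$os_event[1] <- 2
  expect_error(neo_cohort(clin2, pairs), "os_event")
  # mt/wt differing at two positions
  pairs3 <- pairs; pairs3$wt_peptide[1] <- "CCDEFGHIR"
  expect_error(neo_cohort(clin, pairs3), "exactly one")
  # mut_pos inconsistent with the difference
  pairs4 <- pairs; pairs4$mut_pos[1] <- 3L
  expect_error(neo_cohort(clin, pairs4), "mut_pos")
})

test_that("tables round-trip through the TSV readers and writers", {
  dir <- withr::local_tempdir()
  pairs <- toy_pairs()
  clin <- toy_clinical()
  muts <- data.frame(Tumor_Sample_Barcode = "P1", Hugo_Symbol = "EGFR",
                     Variant_Classification = "Missense_Mutation")
  write_peptides(pairs, file.path(dir, "p.tsv"))
  write_clinical(clin, file.path(dir, "c.tsv"))
  write_mutations(muts, file.path(dir, "m.tsv"))
  expect_equal(read_peptides(file.path(dir, "p.tsv")), pairs)
  expect_equal(read_clinical(file.path(dir, "c.tsv")), clin)
  expect_equal(read_mutations(file.path(dir, "m.tsv")), muts)
})
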