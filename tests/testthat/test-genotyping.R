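# Genotype calling from duplicated Ct values.

test_that("mutation-assay calling follows the duplicate-concordance rule", {
  expect_equal(call_mutation_assay(c(24.1, 24.9), ct_max = 35), "positive")
  expect_equal(call_mutation_assay(c(40, 40)), "negative")
  # discordant duplicates are conservative: missing, not positive
  expect_equal(call_mutation_assay(c(24.1, 40)), "missing")
  expect_equal(call_mutation_assay(c(39, 24)), "missing")  # above ct_max
})

test_that("copy-number calling bands delta-Ct into 2/1/0 with control guards", {
  ctrl <- c(22, 22)
  expect_equal(call_copy_number(c(22, 22), ctrl, bands = c(0.5, 1.5)), 2L)
  expect_equal(call_copy_number(c(23, 23), ctrl, bands = c(0.5, 1.5)), 1L)
  expect_equal(call_copy_number(c(40, 40), ctrl), 0L)       # dark with controls up
  expect_true(is.na(call_copy_number(c(22, 22), c(40, 40)))) # control failure
  expect_true(is.na(call_copy_number(c(22, 40), ctrl)))      # discordant
  expect_error(call_copy_number(c(22, 22), ctrl, bands = c(1.5, 0.5)),
               "increasing")
})

test_that("zero-noise simulation round-trips to the exact true genotypes", {
  mk <- panel_markers(6)
  truth <- make_truth(4, mk, c("STIL_TAL1", "CDKN2A"), seed = 2)
  cells <- sample_cells(truth, 1000, seed = 3)
  panel <- make_assay_panel(truth$markers)
  ct <- simulate_ct_readout(cells$genotypes, truth$markers, panel,
                            noise_free(), seed = 4)
  gm <- build_genotype_matrix(ct, truth$markers, panel)
  expect_false(anyNA(gm$genotypes))                      # noise-free completeness
  discordant <- sum(rowSums(gm$genotypes != cells$genotypes) > 0)
  expect_equal(discordant, 0L)
  expect_true(all(gm$qc$controls_passed))
})

test_that("an all-sentinel cell yields all-NA calls and failed controls", {
  mk <- marker_table(c("MUT", "DEL"), c("snv", "cn_loss"))
  panel <- make_assay_panel(mk)
  ct <- data.frame(cell_id = "c1", MUT__rep1 = 40, MUT__rep2 = 40,
                   DEL__rep1 = 40, DEL__rep2 = 40,
                   CTRL__rep1 = 40, CTRL__rep2 = 40)
  gm <- build_genotype_matrix(ct, mk, panel)
  expect_true(all(is.na(gm$genotypes)))
  expect_false(gm$qc$controls_passed)
})

test_that("homozygosity requires a negative paired wild-type-allele assay", {
  mk <- marker_table("PTEN_ex8", "snv", gene = "PTEN")
  panel <- make_assay_panel(mk, wt_allele_for = "PTEN_ex8")
  base <- data.frame(cell_id = c("hom", "het", "nowt"),
                     PTEN_ex8__rep1 = c(24, 24, 24),
                     PTEN_ex8__rep2 = c(24, 24, 24),
                     PTEN_ex8__wt__rep1 = c(40, 25, 40),
                     PTEN_ex8__wt__rep2 = c(40, 25, 25),
                     CTRL__rep1 = 22, CTRL__rep2 = 22)
  gm <- build_genotype_matrix(base, mk, panel)
  expect_equal(unname(gm$genotypes[, 1]), c(2L, 1L, 1L))
  # without a wt assay in the panel, zygosity is capped at het
  panel2 <- make_assay_panel(mk)
  gm2 <- build_genotype_matrix(base[, c(1:3, 6:7)], mk, panel2)
  expect_equal(unname(gm2$genotypes[, 1]), c(1L, 1L, 1L))
})

test_that("calling is permutation-equivariant and monotone in ct_max", {
  mk <- panel_markers(4)
  truth <- make_truth(3, mk, c("STIL_TAL1", "CDKN2A"), seed = 8)
  cells <- sample_cells(truth, 100, seed = 9)
  panel <- make_assay_panel(truth$markers)
  ct <- simulate_ct_readout(cells$genotypes, truth$markers, panel,
                            noise_config(), seed = 10)
  gm <- build_genotype_matrix(ct, truth$markers, panel)
  # permuting rows permutes calls identically
  perm <- rev(seq_len(nrow(ct)))
  gm_perm <- build_genotype_matrix(ct[perm, ], truth$markers, panel)
  expect_equal(gm_perm$genotypes, gm$genotypes[perm, ])
  # lowering ct_max never creates new positives
  gm_low <- build_genotype_matrix(ct, truth$markers, panel, ct_max = 23)
  seqm <- truth$markers$id[truth$markers$class != "cn_loss"]
  was_neg <- gm$genotypes[, seqm] == 0L | is.na(gm$genotypes[, seqm])
  now_pos <- !is.na(gm_low$genotypes[, seqm]) & gm_low$genotypes[, seqm] > 0L
  expect_false(any(was_neg & now_pos))
})

test_that("QC filtering reconciles and matches an independent recount", {
  mk <- panel_markers(4)
  truth <- make_truth(3, mk, c("STIL_TAL1", "CDKN2A"), seed = 20)
  cells <- sample_cells(truth, 1000, seed = 21)
  panel <- make_assay_panel(truth$markers)
  ct <- simulate_ct_readout(cells$genotypes, truth$markers, panel,
                            noise_config(allelic_dropout_rate = 0.1,
                                         assay_failure_rate = 0.1),
                            seed = 22)
  gm <- build_genotype_matrix(ct, truth$markers, panel)
  flt <- qc_filter_cells(gm, max_missing_frac = 0.3)
  r <- flt$report
  expect_equal(r$n_kept + r$n_removed_control_failure + r$n_removed_missing,
               r$n_input)
  # independent recount of the kept fraction from the raw matrix
  keep <- gm$qc$controls_passed &
    rowSums(is.na(gm$genotypes)) / ncol(gm$genotypes) <= 0.3
  expect_equal(r$n_kept, sum(keep))
  expect_equal(nrow(flt$gm$genotypes), sum(keep))
  # identity filter
  flt2 <- qc_filter_cells(flt$gm, max_missing_frac = 1)
  expect_equal(flt2$report$n_kept, flt2$report$n_input)
})
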