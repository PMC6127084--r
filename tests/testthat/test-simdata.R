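# Synthetic-data generator: ground truths, cell sampling, Ct readout,
# xenograft bottlenecks, breakpoint sequences.

test_that("make_truth places truncal markers, is deterministic, validates input", {
  mk <- panel_markers(6)
  truth <- make_truth(4, mk, c("STIL_TAL1", "CDKN2A"), seed = 7)
  # first non-root node carries all truncal markers
  expect_equal(unname(truth$genotypes["C1", c("STIL_TAL1", "CDKN2A")]),
               c(1L, 0L))
  # root is germline
  expect_equal(unname(truth$genotypes["N", ]),
               unname(germline_genotype(truth$markers)))
  # determinism
  truth2 <- make_truth(4, mk, c("STIL_TAL1", "CDKN2A"), seed = 7)
  expect_identical(truth, truth2)
  # degenerate single clone
  t1 <- make_truth(1, marker_table(c("F", "D"), c("fusion", "cn_loss"),
                                   steps = c(1L, 2L)),
                   c("F", "D"), seed = 1)
  expect_equal(nrow(t1$genotypes), 2L)
  expect_equal(unname(t1$frequencies), 1)
  # bad frequency vectors
  expect_error(make_truth(3, mk, "STIL_TAL1", frequencies = c(0.5, 0.5),
                          seed = 1), "length")
  expect_error(make_truth(3, mk, "STIL_TAL1",
                          frequencies = c(0.5, 0.4, 0.2), seed = 1), "sum")
  expect_error(make_truth(2, mk, "NOT_A_MARKER", seed = 1), "subset")
})

test_that("simulated truths always satisfy irreversibility along every path", {
  mk <- panel_markers(8)
  for (seed in 1:20) {
    truth <- make_truth(sample(2:7, 1), mk, c("STIL_TAL1", "CDKN2A"),
                        seed = seed)
    expect_silent(validate_clonal_truth(truth))
  }
})

test_that("reiterative spec creates independent same-gene hits on divergent branches", {
  mk <- panel_markers(4)
  truth <- make_truth(6, mk, c("STIL_TAL1", "CDKN2A"),
                      reiterative_spec = list(list("PTEN", 3)), seed = 11)
  pten <- truth$markers$id[truth$markers$gene == "PTEN"]
  expect_length(pten, 3L)
  # each hit occurs exactly once, and no two hits on the same root-to-leaf
  # path: the nodes where each hit is present must not be nested
  S <- truth$genotypes[, pten, drop = FALSE]
  carriers <- lapply(pten, function(p) which(S[, p] > 0))
  for (a in 1:2) for (b in (a + 1):3) {
    expect_length(intersect(carriers[[a]], carriers[[b]]), 0L)
  }
})

test_that("sample_cells draws clones at their specified frequencies", {
  mk <- panel_markers(2)
  # identical rows for a single clone
  t1 <- make_truth(1, marker_table(c("F", "D"), c("fusion", "cn_loss"),
                                   steps = c(1, 2)), c("F", "D"), seed = 1)
  cs <- sample_cells(t1, 10, seed = 2)
  expect_equal(nrow(unique(cs$genotypes)), 1L)
  # binomial 3-sigma bound at n = 10,000 for frequencies (0.5, 0.5)
  t2 <- make_truth(2, mk, c("STIL_TAL1", "CDKN2A"),
                   frequencies = c(0.5, 0.5), seed = 3)
  cs2 <- sample_cells(t2, 10000, seed = 4)
  n1 <- sum(cs2$clone == "C1")
  expect_lt(abs(n1 - 5000), 3 * sqrt(10000 * 0.25))
  # cells carry exactly their clone's genotype
  i <- match(cs2$clone, rownames(t2$genotypes))
  expect_equal(unname(cs2$genotypes), unname(t2$genotypes[i, ]))
  expect_error(sample_cells(t2, 0, seed = 1), "positive")
})

test_that("noise-free Ct readout follows the closed-form delta-Ct model", {
  mk <- marker_table(c("MUT", "DEL"), c("snv", "cn_loss"))
  panel <- make_assay_panel(mk)
  nz <- noise_free()
  # wt cell: mutation assay never amplifies
  G <- matrix(c(0L, 1L), 1, 2, dimnames = list("c1", mk$id))
  ct <- simulate_ct_readout(G, mk, panel, nz, seed = 1)
  expect_equal(ct$MUT__rep1, nz$no_amp_sentinel)
  expect_equal(ct$MUT__rep2, nz$no_amp_sentinel)
  # one copy: Ct exactly baseline + one shift
  expect_equal(ct$DEL__rep1, nz$ct_baseline + nz$ct_per_copy_shift)
  expect_equal(ct$DEL__rep2, nz$ct_baseline + nz$ct_per_copy_shift)
  expect_equal(ct$CTRL__rep1, nz$ct_baseline)
  # total dropout: every allele-dependent assay reads the sentinel
  ado1 <- noise_config(allelic_dropout_rate = 1, assay_failure_rate = 0,
                       ct_sd = 0)
  G2 <- matrix(c(1L, 1L), 1, 2, dimnames = list("c1", mk$id))
  ct2 <- simulate_ct_readout(G2, mk, panel, ado1, seed = 1)
  expect_equal(ct2$MUT__rep1, ado1$no_amp_sentinel)
  expect_equal(ct2$DEL__rep1, ado1$no_amp_sentinel)
  # control assay is unaffected by dropout
  expect_equal(ct2$CTRL__rep1, ado1$ct_baseline)
  # marker without an assay is a configuration error
  expect_error(simulate_ct_readout(G, mk, panel[-1, ], nz, seed = 1),
               "without an assay")
})

test_that("xenograft resampling supports sweeps, re-weighting and validation", {
  mk <- panel_markers(4)
  truth <- make_truth(3, mk, c("STIL_TAL1", "CDKN2A"), seed = 5)
  # single-clone sweep
  xg <- simulate_xenograft(truth, engrafting_clones = c(C2 = 1),
                           n_cells = 200, seed = 6)
  expect_true(all(xg$clone == "C2"))
  # weights equal to diagnostic frequencies: statistically indistinguishable
  xg2 <- simulate_xenograft(truth, engrafting_clones = truth$frequencies,
                            n_cells = 5000, seed = 7)
  cs <- sample_cells(truth, 5000, seed = 8)
  tab <- rbind(table(factor(xg2$clone, names(truth$frequencies))),
               table(factor(cs$clone, names(truth$frequencies))))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
  # unknown clone / empty set errors
  expect_error(simulate_xenograft(truth, engrafting_clones = c(C9 = 1),
                                  n_cells = 10, seed = 1), "absent")
  expect_error(simulate_xenograft(truth,
                                  engrafting_clones = setNames(numeric(0),
                                                               character(0)),
                                  n_cells = 10, seed = 1), "empty")
  # selection strength favours the most mutated clones (ties allowed)
  xg3 <- simulate_xenograft(truth, selection_strength = 3, n_cells = 2000,
                            seed = 9)
  S <- truth$genotypes[-1, ]
  cn <- truth$markers$class == "cn_loss"
  S[, cn] <- 2L - S[, cn]
  changes <- rowSums(S)
  deepest <- names(changes)[changes == max(changes)]
  expect_true(names(which.max(table(xg3$clone))) %in% deepest)
})

test_that("breakpoint sequences embed motifs at recorded offsets and are reproducible", {
  bp <- make_breakpoint_sequences(5, 120, embed = "consensus_rss",
                                  spacer = 23, seed = 42)
  expect_equal(length(bp$sequences), 5L)
  for (i in 1:5) {
    s <- as.character(bp$sequences[[i]])
    motif <- substr(s, bp$info$start[i] + 1, bp$info$end[i])
    if (bp$info$strand[i] == "-")
      motif <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif)))
    expect_equal(substr(motif, 1, 7), "CACAGTG")
    expect_equal(substr(motif, 31, 39), "ACAAAAACC")
  }
  # byte-identical reproduction under the same seed
  bp2 <- make_breakpoint_sequences(5, 120, embed = "consensus_rss",
                                   spacer = 23, seed = 42)
  expect_identical(as.character(bp$sequences), as.character(bp2$sequences))
  # too-short sequence refused
  expect_error(make_breakpoint_sequences(1, 30, embed = "consensus_rss",
                                         spacer = 23, seed = 1), "too small")
})

test_that("background heptamer occurrences match the uniform-sequence expectation", {
  n <- 100; L <- 500
  bp <- make_breakpoint_sequences(n, L, embed = "none", seed = 13)
  observed <- sum(vapply(seq_len(n), function(i)
    length(Biostrings::matchPattern("CACAGTG",
                                    bp$sequences[[i]])), integer(1)))
  expected <- n * (L - 6) / 4^7
  expect_lt(abs(observed - expected), 3 * sqrt(expected) + 1)
})
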