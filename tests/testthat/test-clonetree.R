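# Subclone collapsing and maximum-parsimony tree inference.

test_that("collapse merges identical rows and conserves counts", {
  mk <- marker_table(c("A", "B"), "snv")
  G <- matrix(rep(c(1L, 0L), each = 10), 10, 2,
              dimnames = list(sprintf("c%d", 1:10), mk$id))
  sc <- collapse_subclones(genotype_matrix(G, mk), min_cells = 1)
  expect_equal(nrow(sc$genotypes), 1L)
  expect_equal(unname(sc$frequencies), 1)

  # {A x6, B x3, C x1} at min_cells = 2 -> two subclones, one below threshold
  G2 <- rbind(matrix(rep(c(1L, 0L), 6), 6, 2, byrow = TRUE),
              matrix(rep(c(1L, 1L), 3), 3, 2, byrow = TRUE),
              matrix(c(0L, 1L), 1, 2))
  rownames(G2) <- sprintf("c%d", 1:10)
  sc2 <- collapse_subclones(genotype_matrix(G2, mk), min_cells = 2)
  expect_equal(unname(sc2$counts), c(6L, 3L))
  expect_equal(sum(sc2$below_threshold$count), 1L)
  expect_equal(sum(sc2$counts) + sc2$n_unassigned +
                 sum(sc2$below_threshold$count), 10L)
  expect_error(collapse_subclones(
    genotype_matrix(G2[0, , drop = FALSE], mk)), "empty")
})

test_that("NA rows are assigned only when exactly one subclone is compatible", {
  mk <- marker_table(c("A", "B", "C"), "snv")
  G <- rbind(matrix(rep(c(1L, 0L, 0L), 5), 5, 3, byrow = TRUE),   # clone A
             matrix(rep(c(1L, 1L, 1L), 5), 5, 3, byrow = TRUE),   # clone B
             c(1L, NA, 0L),    # only compatible with A (C = 0)
             c(1L, NA, NA))    # compatible with both -> unassigned
  rownames(G) <- sprintf("c%d", 1:12)
  sc <- collapse_subclones(genotype_matrix(G, mk), min_cells = 2)
  # brute-force compatibility check of the NA row against both genotypes
  expect_true(all(c(1L, 0L)[c(TRUE, FALSE)] ==
                    sc$genotypes[1, c("A")]))
  expect_equal(sort(unname(sc$counts)), c(5L, 6L))
  expect_equal(sc$n_unassigned, 1L)
})

test_that("single-dropout satellite classes can be absorbed into their clone", {
  mk <- marker_table(c("A", "B", "C"), "snv")
  big <- matrix(rep(c(1L, 1L, 0L), 30), 30, 3, byrow = TRUE)
  sat <- matrix(rep(c(1L, 0L, 0L), 4), 4, 3, byrow = TRUE)  # B dropped out
  G <- rbind(big, sat)
  rownames(G) <- sprintf("c%d", seq_len(nrow(G)))
  sc_off <- collapse_subclones(genotype_matrix(G, mk), min_cells = 2)
  expect_equal(nrow(sc_off$genotypes), 2L)
  sc_on <- collapse_subclones(genotype_matrix(G, mk), min_cells = 2,
                              absorb_dropout_classes = TRUE)
  expect_equal(nrow(sc_on$genotypes), 1L)
  expect_equal(unname(sc_on$counts), 34L)
  # absorption never runs against the dropout direction (gain of a marker)
  gain <- matrix(rep(c(1L, 1L, 1L), 4), 4, 3, byrow = TRUE)
  G2 <- rbind(big, gain)
  rownames(G2) <- sprintf("c%d", seq_len(nrow(G2)))
  sc_gain <- collapse_subclones(genotype_matrix(G2, mk), min_cells = 2,
                                absorb_dropout_classes = TRUE)
  expect_equal(nrow(sc_gain$genotypes), 2L)
})

test_that("parsimony score counts unit changes and equals branch-length sum", {
  mk <- marker_table(c("F", "DEL"), c("fusion", "cn_loss"), steps = c(1, 2))
  sc <- subclone_set(matrix(c(1L, 0L), 1, 2), mk)
  trees <- infer_parsimony_trees(sc)
  # fusion (1) + two copy losses (2) = 3
  expect_equal(attr(trees, "score"), 3L)
  expect_equal(parsimony_score(trees[[1]]), 3L)
  expect_equal(sum(trees[[1]]$edges$length), 3L)

  # star tree over k clones with one private mutation each scores k
  mk2 <- marker_table(sprintf("M%d", 1:4), "snv")
  G <- diag(4); mode(G) <- "integer"
  star <- infer_parsimony_trees(subclone_set(G, mk2))
  expect_equal(attr(star, "score"), 4L)

  # random valid trees: score equals the independent per-edge recount
  for (seed in 1:5) {
    sc_r <- random_subclone_set(5, 6, seed)
    tr <- infer_parsimony_trees(sc_r)
    for (t in tr[seq_len(min(3, length(tr)))])
      expect_equal(parsimony_score(t), recount_score(t))
  }
})

test_that("chain-compatible genotypes give the unique linear perfect phylogeny", {
  mk <- marker_table(c("M1", "M2", "M3"), "snv")
  G <- rbind(g1 = c(1L, 0L, 0L), g2 = c(1L, 1L, 0L), g3 = c(1L, 1L, 1L))
  trees <- infer_parsimony_trees(subclone_set(G, mk))
  expect_length(trees, 1L)
  expect_equal(attr(trees, "score"), 3L)
  e <- trees[[1]]$edges
  expect_equal(e$parent[match(c("g1", "g2", "g3"), e$child)],
               c("N", "g1", "g2"))
})

test_that("shared markers of incompatible clones go to an inferred ancestor", {
  mk <- marker_table(c("F", "DEL", "P1", "P2"),
                     c("fusion", "cn_loss", "snv", "snv"),
                     steps = c(1, 2, 1, 1))
  G <- rbind(Ca = c(1L, 0L, 1L, 0L), Cb = c(1L, 0L, 0L, 1L))
  trees <- infer_parsimony_trees(subclone_set(G, mk))
  expect_length(trees, 1L)
  tree <- trees[[1]]
  anc <- tree$nodes$id[tree$nodes$inferred]
  expect_length(anc, 1L)
  # the inferred ancestor carries exactly the shared truncal markers
  expect_equal(unname(tree$genotypes[anc, ]), c(1L, 0L, 0L, 0L))
  expect_equal(attr(trees, "score"), 5L)
})

test_that("the published-style reiterative case yields exactly two co-optimal trees", {
  trees <- infer_parsimony_trees(fixture_6116())
  expect_length(trees, 2L)
  expect_equal(attr(trees, "score"), 7L)
  # the two trees differ only in the parent of the latest clone C5
  p5 <- sort(vapply(trees, function(t)
    t$edges$parent[t$edges$child == "C5"], character(1)))
  expect_equal(p5, c("C3", "C4"))
  shared <- lapply(trees, function(t)
    t$edges[t$edges$child != "C5", c("parent", "child")])
  expect_identical(shared[[1]], shared[[2]])
})

test_that("reiterative origin counts match a brute-force edge scan", {
  trees <- infer_parsimony_trees(fixture_6116())
  reit <- detect_reiterative_events(trees)
  # minimum over the two co-optimal trees: either FREM2 or PIK3CD could be
  # the doubly-hit gene, so neither is unambiguously reiterative
  expect_equal(reit$n_origins[reit$gene == "FREM2"], 1L)
  expect_equal(reit$n_origins[reit$gene == "PIK3CD"], 1L)
  # per single tree, the recount oracle: count edges with a change per gene
  t1 <- trees[[1]]
  reit1 <- detect_reiterative_events(t1)
  for (g in reit1$gene) {
    mids <- t1$markers$id[t1$markers$gene == g]
    cnt <- sum(vapply(seq_len(nrow(t1$edges)), function(i) {
      d <- t1$genotypes[t1$edges$child[i], mids] -
        t1$genotypes[t1$edges$parent[i], mids]
      cn <- t1$markers$class[t1$markers$gene == g] == "cn_loss"
      any(ifelse(cn, d < 0, d > 0))
    }, logical(1)))
    expect_equal(reit1$n_origins[reit1$gene == g], cnt)
  }
  # a truth with 4 planted independent PTEN hits recovers 4 origins
  mk <- panel_markers(4)
  truth <- make_truth(6, mk, c("STIL_TAL1", "CDKN2A"),
                      reiterative_spec = list(list("PTEN", 4)), seed = 3)
  sc <- subclone_set(truth$genotypes[-1, ], truth$markers)
  tr <- infer_parsimony_trees(sc, max_subclones = 9)
  reit2 <- detect_reiterative_events(tr)
  expect_equal(reit2$n_origins[reit2$gene == "PTEN"], 4L)
  expect_true(reit2$reiterative[reit2$gene == "PTEN"])
})

test_that("inferred scores equal the brute-force oracle on random instances", {
  for (seed in 1:25) {
    k <- (seed %% 6) + 2          # 2..7 subclones
    m <- (seed %% 8) + 3          # 3..10 markers
    sc <- random_subclone_set(k, m, seed)
    expect_equal(attr(infer_parsimony_trees(sc), "score"),
                 brute_force_min_score(sc),
                 info = sprintf("seed %d (k=%d, m=%d)", seed, k, m))
  }
  expect_error(brute_force_min_score(random_subclone_set(8, 4, 1)),
               "refusing")
})

test_that("genotypes outside the irreversible state space are rejected", {
  mk <- marker_table(c("A", "DEL"), c("snv", "cn_loss"))
  expect_error(subclone_set(matrix(c(1L, 3L), 1, 2), mk), "invalid")
  expect_error(subclone_set(matrix(c(1L, 1L, 1L, 1L), 2, 2), mk), "distinct")
})

test_that("truncal markers land on the single root edge", {
  mk <- panel_markers(6)
  for (seed in 1:10) {
    truth <- make_truth(5, mk, c("STIL_TAL1", "CDKN2A"), seed = seed)
    sc <- subclone_set(truth$genotypes[-1, ], truth$markers)
    trees <- infer_parsimony_trees(sc)
    for (t in trees)
      expect_true(truncal_on_root_edge(t, c("STIL_TAL1", "CDKN2A")))
  }
})

test_that("bootstrap supports are deterministic, bounded, and high for clean data", {
  mk <- panel_markers(4)
  truth <- make_truth(3, mk, c("STIL_TAL1", "CDKN2A"), seed = 31)
  cells <- sample_cells(truth, 200, seed = 32)
  gm <- genotype_matrix(cells$genotypes, truth$markers)
  bt <- bootstrap_support(gm, n_reps = 50, seed = 33)
  expect_true(all(bt$nodes$support >= 0 & bt$nodes$support <= 100))
  # noise-free, well-separated clones: every observed clade near-certain
  expect_true(all(bt$nodes$support[bt$nodes$cell_count > 0] >= 95))
  # fixed seed reproduces supports exactly
  bt2 <- bootstrap_support(gm, n_reps = 50, seed = 33)
  expect_identical(bt$nodes$support, bt2$nodes$support)
  # a single replicate can only give 0 or 100
  bt3 <- bootstrap_support(gm, n_reps = 1, seed = 34)
  expect_true(all(bt3$nodes$support %in% c(0, 100)))
})

test_that("noisy simulations recover the true topology (small replicate)", {
  res <- recovery_experiment(n_seeds = 10, seed = 5)
  expect_gte(res$recovery_rate, 0.8)
  expect_equal(res$truncal_rate, 1)
})
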