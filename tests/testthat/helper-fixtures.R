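# Shared fixture builders (all data generated in code).

# fusion + bi-allelic CDKN2A truncal pair plus n_snv subclonal SNV markers
panel_markers <- function(n_snv = 6L, genes = sprintf("GENE%d", seq_len(n_snv))) {
  rbind(marker_table(c("STIL_TAL1", "CDKN2A"), c("fusion", "cn_loss"),
                     steps = c(1L, 2L)),
        marker_table(sprintf("SNV_%d", seq_len(n_snv)), "snv", gene = genes))
}

# subclone genotypes mirroring the published 6116 case: truncal fusion +
# homozygous CDKN2A deletion, subclonal NOTCH1, FREM2 / PIK3CD branches,
# and a latest clone carrying both FREM2 and PIK3CD
fixture_6116 <- function() {
  mk <- marker_table(
    id = c("STIL_TAL1", "CDKN2A", "NOTCH1", "FREM2", "PIK3CD"),
    class = c("fusion", "cn_loss", "snv", "snv", "snv"),
    steps = c(1L, 2L, 1L, 1L, 1L))
  G <- rbind(C1 = c(1L, 0L, 0L, 0L, 0L),
             C2 = c(1L, 0L, 1L, 0L, 0L),
             C3 = c(1L, 0L, 1L, 1L, 0L),
             C4 = c(1L, 0L, 1L, 0L, 1L),
             C5 = c(1L, 0L, 1L, 1L, 1L))
  subclone_set(G, mk, counts = c(120L, 80L, 50L, 40L, 18L))
}

# random valid subclone set on a mixed marker panel (steps sampled, so
# genotypes always respect the irreversible state space)
random_subclone_set <- function(k, m, seed) {
  with_seed_test(seed, {
    mk <- marker_table(sprintf("M%d", seq_len(m)),
                       ifelse(stats::runif(m) < 0.3, "cn_loss", "snv"))
    repeat {
      S <- matrix(sample(0:2, k * m, replace = TRUE, prob = c(.5, .35, .15)),
                  k, m)
      if (!anyDuplicated(apply(S, 1L, paste, collapse = ","))) break
    }
    G <- S
    cn <- mk$class == "cn_loss"
    G[, cn] <- 2L - S[, cn]
    subclone_set(G, mk)
  })
}

# seed-scoped RNG for helpers (tests otherwise rely on function seeds)
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# independent per-edge recount of a clone tree's changes (ordered Hamming)
recount_score <- function(tree) {
  raw <- tree$genotypes
  cn <- tree$markers$class == "cn_loss"
  steps <- raw
  steps[, cn] <- 2L - raw[, cn]
  tot <- 0L
  for (i in seq_len(nrow(tree$edges))) {
    p <- steps[tree$edges$parent[i], ]
    c <- steps[tree$edges$child[i], ]
    stopifnot(all(c - p >= 0))
    tot <- tot + sum(c - p)
  }
  tot
}
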