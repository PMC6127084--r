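## Simulation experiment: can the pipeline recover a known clonal
## topology from noisy single-cell readouts?

truth_edge_keys <- function(truth) {
  keys <- apply(truth$genotypes, 1L, geno_key)
  sort(vapply(seq_along(truth$parent)[-1L], function(v)
    paste(keys[truth$parent[v]], keys[v], sep = " > "), character(1)))
}

tree_edge_keys <- function(tree) {
  keys <- apply(tree$genotypes, 1L, geno_key)
  names(keys) <- rownames(tree$genotypes)
  sort(vapply(seq_len(nrow(tree$edges)), function(i)
    paste(keys[tree$edges$parent[i]], keys[tree$edges$child[i]], sep = " > "),
    character(1)))
}

#' Does a clone tree match a simulated truth exactly?
#'
#' Compares the (parent genotype, child genotype) edge multisets, i.e.
#' full topology including inferred ancestors.
#'
#' @param tree a `clone_tree`.
#' @param truth a `clonal_truth`.
#' @return logical.
#' @export
same_topology <- function(tree, truth) {
  identical(tree_edge_keys(tree), truth_edge_keys(truth))
}

#' Are all truncal markers confined to the root edge?
#'
#' A truncal marker (non-wild-type in every subclone) must change only on
#' the single edge leaving the germline root.
#'
#' @param tree a `clone_tree`.
#' @param truncal_markers marker ids expected on the root edge.
#' @return logical.
#' @export
truncal_on_root_edge <- function(tree, truncal_markers) {
  S <- geno_to_steps(tree$genotypes, tree$markers)
  js <- match(truncal_markers, tree$markers$id)
  for (i in seq_len(nrow(tree$edges))) {
    d <- S[tree$edges$child[i], js] - S[tree$edges$parent[i], js]
    if (any(d > 0) && tree$edges$parent[i] != tree$root) return(FALSE)
    if (tree$edges$parent[i] == tree$root && any(d <= 0)) return(FALSE)
  }
  TRUE
}

#' Topology-recovery simulation experiment
#'
#' For each seed: build a random clonal truth with a truncal fusion plus
#' bi-allelic CDKN2A-style loss and two subclonal SNV markers per later
#' edge, sample cells, simulate the duplicated Ct readout under allelic
#' dropout and assay failure, call genotypes, QC-filter, collapse
#' subclones and infer the maximum-parsimony tree; then record whether
#' the co-optimal set contains the true topology and whether the truncal
#' markers sit on the root edge.
#'
#' `min_cells` defaults to 20 of 300 cells (~7%): under per-allele
#' dropout, genotype classes created by a single miscalled marker reach
#' roughly 5-10 cells per 60-cell clone, so 20 separates true subclones
#' from dropout artifact classes ("below the level of reliable
#' detection").
#'
#' @param n_seeds number of independent simulations.
#' @param n_subclones subclones per truth (default 5).
#' @param n_cells cells per simulation (default 300).
#' @param ado allelic dropout rate (default 0.1).
#' @param failure per-well assay failure rate (default 0.05).
#' @param min_cells subclone detection threshold (default 20).
#' @param seed base seed; simulation r uses `seed + r` offsets.
#' @return list with `recovered` and `truncal_ok` logical vectors,
#'   `recovery_rate` and `truncal_rate` (fractions over seeds for which
#'   a tree was recovered).
#' @export
recovery_experiment <- function(n_seeds = 50L, n_subclones = 5L,
                                n_cells = 300L, ado = 0.1, failure = 0.05,
                                min_cells = 20L, seed = 1L) {
  markers <- rbind(
    marker_table(c("STIL_TAL1", "CDKN2A"), c("fusion", "cn_loss"),
                 steps = c(1L, 2L)),
    marker_table(sprintf("SNV_%d", seq_len(2L * (n_subclones - 1L))), "snv",
                 gene = sprintf("GENE%d", seq_len(2L * (n_subclones - 1L)))))
  recovered <- truncal_ok <- logical(n_seeds)
  for (r in seq_len(n_seeds)) {
    s <- seed + 1000L * r
    truth <- make_truth(n_subclones, markers,
                        truncal_markers = c("STIL_TAL1", "CDKN2A"),
                        seed = s)
    cells <- sample_cells(truth, n_cells, seed = s + 1L)
    panel <- make_assay_panel(truth$markers)
    noise <- noise_config(allelic_dropout_rate = ado,
                          assay_failure_rate = failure)
    ct <- simulate_ct_readout(cells$genotypes, truth$markers, panel, noise,
                              seed = s + 2L)
    gm <- build_genotype_matrix(ct, truth$markers, panel)
    flt <- qc_filter_cells(gm, max_missing_frac = 0.5)
    sc <- collapse_subclones(flt$gm, min_cells = min_cells,
                             absorb_dropout_classes = TRUE)
    if (nrow(sc$genotypes) < 1L || nrow(sc$genotypes) > 9L) {
      recovered[r] <- truncal_ok[r] <- FALSE
      next
    }
    trees <- infer_parsimony_trees(sc)
    hit <- vapply(trees, same_topology, logical(1), truth = truth)
    recovered[r] <- any(hit)
    best <- if (any(hit)) trees[[which(hit)[1L]]] else trees[[1L]]
    truncal_ok[r] <- truncal_on_root_edge(best, c("STIL_TAL1", "CDKN2A"))
  }
  list(recovered = recovered, truncal_ok = truncal_ok,
       recovery_rate = mean(recovered),
       truncal_rate = mean(truncal_ok[recovered]))
}
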