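## The clone_tree container: a rooted clonal phylogeny whose nodes are
## observed or inferred subclones with full genotypes, whose edges are
## labelled with the unit state changes they carry, and whose branch
## lengths equal the number of evolutionary changes (so the sum of branch
## lengths is the parsimony score).

## Contract zero-change edges of a labelled binary topology and assemble a
## clone_tree. parent: topology parent vector; labels: node x m steps.
build_clone_tree <- function(parent, labels, sc) {
  k <- nrow(sc$genotypes)
  ord <- topology_orders(parent)
  n_nodes <- length(parent)

  comp <- rep(NA_integer_, n_nodes)
  comp[1L] <- 1L
  n_comp <- 1L
  for (v in ord$preorder) {
    if (v == 1L) next
    if (all(labels[v, ] == labels[parent[v], ])) {
      comp[v] <- comp[parent[v]]
    } else {
      n_comp <- n_comp + 1L
      comp[v] <- n_comp
    }
  }

  m <- ncol(labels)
  comp_steps <- matrix(0L, n_comp, m)
  comp_obs <- rep(NA_integer_, n_comp)      # subclone index if observed
  for (v in c(1L, ord$preorder[-1L])) {
    comp_steps[comp[v], ] <- labels[v, ]
    if (v >= 2L && v <= k + 1L) comp_obs[comp[v]] <- v - 1L
  }
  comp_parent <- rep(NA_integer_, n_comp)
  for (v in ord$preorder) {
    if (v == 1L) next
    if (comp[v] != comp[parent[v]]) comp_parent[comp[v]] <- comp[parent[v]]
  }

  ## deterministic ids: root "N"; observed keep their subclone names;
  ## inferred ancestors A1, A2, ... ordered by (change count, genotype key)
  markers <- sc$markers
  comp_geno <- steps_to_geno(comp_steps, markers)
  colnames(comp_geno) <- markers$id
  keys <- apply(comp_geno, 1L, geno_key)
  ids <- character(n_comp)
  ids[1L] <- "N"
  obs <- which(!is.na(comp_obs) & seq_len(n_comp) != 1L)
  ids[obs] <- rownames(sc$genotypes)[comp_obs[obs]]
  inf <- which(is.na(comp_obs) & seq_len(n_comp) != 1L)
  if (length(inf)) {
    o <- order(rowSums(comp_steps[inf, , drop = FALSE]), keys[inf])
    ids[inf[o]] <- paste0("A", seq_along(inf))
  }

  counts <- ifelse(is.na(comp_obs), 0L, sc$counts[comp_obs])
  counts[is.na(counts)] <- 0L

  edges <- data.frame(parent = character(0), child = character(0),
                      length = integer(0), changes = character(0),
                      stringsAsFactors = FALSE)
  for (cmp in seq_len(n_comp)[-1L]) {
    p <- comp_parent[cmp]
    d <- comp_steps[cmp, ] - comp_steps[p, ]
    chg <- vapply(which(d > 0), function(j)
      describe_change(markers[j, ], comp_geno[p, j], comp_geno[cmp, j]),
      character(1))
    edges <- rbind(edges, data.frame(
      parent = ids[p], child = ids[cmp], length = sum(d),
      changes = paste(chg, collapse = ";"), stringsAsFactors = FALSE))
  }
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(id = ids, genotype_key = keys,
                      observed = !is.na(comp_obs) | counts > 0L,
                      inferred = is.na(comp_obs) & seq_len(n_comp) != 1L,
                      cell_count = as.integer(counts),
                      frequency = as.numeric(counts) / max(1L, sc$n_total),
                      support = NA_real_, stringsAsFactors = FALSE)
  nodes$observed[1L] <- !is.na(comp_obs[1L])
  o <- order(match(nodes$id, c("N", sort(ids[-1L]))))
  nodes <- nodes[o, , drop = FALSE]
  rownames(nodes) <- NULL
  comp_geno <- comp_geno[o, , drop = FALSE]
  rownames(comp_geno) <- nodes$id

  parent_map <- setNames(rep(NA_character_, n_comp), nodes$id)
  parent_map[edges$child] <- edges$parent

  ## canonical identity: sorted (parent genotype, child genotype) multiset
  key_of <- setNames(nodes$genotype_key, nodes$id)
  canon <- paste(sort(paste(key_of[edges$parent], key_of[edges$child],
                            sep = " > ")), collapse = " | ")

  structure(list(nodes = nodes, genotypes = comp_geno, edges = edges,
                 parent = parent_map, markers = markers, root = "N",
                 n_total_cells = sc$n_total),
            class = "clone_tree", canonical_key = canon)
}

#' @export
print.clone_tree <- function(x, ...) {
  n_inf <- sum(x$nodes$inferred)
  cat(sprintf("clone_tree: %d nodes (%d inferred), parsimony score %d\n",
              nrow(x$nodes), n_inf, parsimony_score(x)))
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s -> %s  [%d change%s] %s\n", e$parent, e$child,
                e$length, if (e$length == 1) "" else "s", e$changes))
  }
  invisible(x)
}

children_of <- function(tree, id) tree$edges$child[tree$edges$parent == id]

#' Serialise a clone tree to Newick
#'
#' Branch lengths are the per-edge change counts; node labels are the
#' subclone ids, with bootstrap support (when present) appended after
#' `#` (e.g. `C2#97`). Chains of single-child nodes are preserved.
#'
#' @param tree a `clone_tree`.
#' @return Newick string.
#' @export
clone_tree_newick <- function(tree) {
  lab <- function(id) {
    s <- tree$nodes$support[tree$nodes$id == id]
    if (length(s) && !is.na(s)) sprintf("%s#%g", id, s) else id
  }
  rec <- function(id) {
    kids <- children_of(tree, id)
    len <- tree$edges$length[tree$edges$child == id]
    base <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
             ")", lab(id))
    else lab(id)
    if (length(len)) paste0(base, ":", len) else base
  }
  paste0(rec(tree$root), ";")
}

#' Bootstrap support for the best maximum-parsimony clone tree
#'
#' Resamples cells (rows of the genotype matrix) with replacement,
#' re-collapses and re-infers per replicate, and annotates each node of
#' the full-data best tree with the percentage of replicates whose
#' co-optimal trees contain a node with the same genotype (the same set of
#' acquired markers). Cell resampling, rather than character resampling,
#' is used because the marker panels are small (5-10 markers) and the
#' relevant sampling noise is in clone frequencies.
#'
#' @param gm a [genotype_matrix()] of kept cells.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; fixed seed gives identical supports.
#' @param min_cells passed to [collapse_subclones()].
#' @param max_subclones passed to [infer_parsimony_trees()]; replicates
#'   that exceed the bound are counted as unsupportive.
#' @return The best full-data `clone_tree` (first in canonical order) with
#'   `nodes$support` filled in (0-100), and attribute `n_reps`.
#' @export
bootstrap_support <- function(gm, n_reps = 100L, seed = 1L, min_cells = 2L,
                              max_subclones = 9L) {
  abort_if(!is_count(n_reps), "n_reps must be >= 1")
  sc <- collapse_subclones(gm, min_cells = min_cells)
  trees <- infer_parsimony_trees(sc, max_subclones = max_subclones)
  best <- trees[[1L]]

  rep_keys <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(nrow(gm$genotypes), replace = TRUE)
      gmr <- genotype_matrix(gm$genotypes[idx, , drop = FALSE], gm$markers,
                             qc = gm$qc[idx, , drop = FALSE])
      rownames(gmr$genotypes) <- sprintf("r%d", seq_along(idx))
      scr <- tryCatch(collapse_subclones(gmr, min_cells = min_cells),
                      error = function(e) NULL)
      if (is.null(scr) || nrow(scr$genotypes) == 0L ||
          nrow(scr$genotypes) > max_subclones) return(character(0))
      tr <- infer_parsimony_trees(scr, max_subclones = max_subclones)
      unique(unlist(lapply(tr, function(t) t$nodes$genotype_key)))
    })
  })
  support <- vapply(best$nodes$genotype_key, function(key)
    100 * mean(vapply(rep_keys, function(ks) key %in% ks, logical(1))),
    numeric(1))
  best$nodes$support <- as.numeric(support)
  attr(best, "n_reps") <- as.integer(n_reps)
  best
}
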