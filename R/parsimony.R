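## Maximum-parsimony clone trees under an ordered irreversible character
## model (Camin-Sokal style): sequence markers step 0->1->2, copy numbers
## 2->1->0, unit cost per step, reversal cost infinite. The germline state
## roots every tree. Observed subclone genotypes may occupy internal
## positions; ancestral (inferred) subclones are introduced only when they
## reduce the score.
##
## Search: exhaustive enumeration of rooted binary leaf topologies (the
## germline treated as an extra fixed taxon), per-character Sankoff dynamic
## programming under the asymmetric cost matrix, then contraction of
## zero-change edges. Feasible because cases carry <= ~8 subclones, and it
## guarantees the co-optimal set is complete.

.topo_cache <- new.env(parent = emptyenv())

## All rooted-at-germline binary leaf topologies for k subclone leaves.
## Nodes: 1 = germline root, 2..k+1 = subclone leaves, k+2..2k = internal.
## Built by inserting each new leaf on every existing edge; (2k-3)!! trees.
enumerate_topologies <- function(k) {
  key <- as.character(k)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  n_nodes <- 2L * k
  base <- rep(NA_integer_, n_nodes)
  base[2L] <- 1L
  topos <- list(base)
  if (k >= 2L) for (j in 2:k) {
    leaf <- j + 1L
    internal <- k + j
    out <- vector("list", length(topos) * (2L * j - 3L))
    idx <- 0L
    for (p in topos) {
      for (v in which(!is.na(p))) {      # every edge v -> parent[v]
        q <- p
        q[internal] <- q[v]
        q[v] <- internal
        q[leaf] <- internal
        idx <- idx + 1L
        out[[idx]] <- q
      }
    }
    topos <- out
  }
  .topo_cache[[key]] <- topos
  topos
}

## traversal orders are instance-independent: cache them with the topologies
enumerate_topology_orders <- function(k) {
  key <- paste0("ord", k)
  if (is.null(.topo_cache[[key]]))
    .topo_cache[[key]] <- lapply(enumerate_topologies(k), topology_orders)
  .topo_cache[[key]]
}

## children lists and a postorder (children before parents) for a topology
topology_orders <- function(parent) {
  nodes <- which(!is.na(parent))
  kids <- vector("list", length(parent))   # indexed by node id
  for (v in nodes) kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  po <- integer(0)
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    po <- c(po, v)
    ch <- kids[[v]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  list(kids = kids, preorder = po, postorder = rev(po))
}

BIG_COST <- 1e9

## Sankoff DP on one topology. leaf_steps: k x m steps matrix (subclone i
## at node i+1); irreversible cost t-s for t>=s, infinite otherwise.
## Returns minimum score and the optimal node labels (steps scale).
leaf_cost_matrices <- function(leaf_steps) {
  m <- ncol(leaf_steps)
  lapply(seq_len(nrow(leaf_steps)), function(i) {
    fm <- matrix(BIG_COST, 3L, m)
    fm[cbind(leaf_steps[i, ] + 1L, seq_len(m))] <- 0
    fm
  })
}

sankoff_topology <- function(parent, leaf_steps, want_labels = TRUE,
                             ord = topology_orders(parent),
                             leaf_f = leaf_cost_matrices(leaf_steps)) {
  k <- nrow(leaf_steps)
  m <- ncol(leaf_steps)
  n_nodes <- length(parent)
  f <- vector("list", n_nodes)            # per node: 3 x m cost-to-go
  f[1L + seq_len(k)] <- leaf_f
  for (v in ord$postorder) {
    if (v <= k + 1L) next                  # root or leaf
    a1 <- a2 <- a3 <- 0
    for (c in ord$kids[[v]]) {
      fc <- f[[c]]
      ## g[s] = min over t >= s of (t - s + fc[t]):
      ## g3 = fc3; g2 = min(fc2, g3+1); g1 = min(fc1, g2+1)
      g3 <- fc[3L, ]
      g2 <- pmin(fc[2L, ], g3 + 1)
      g1 <- pmin(fc[1L, ], g2 + 1)
      a1 <- a1 + g1
      a2 <- a2 + g2
      a3 <- a3 + g3
    }
    f[[v]] <- matrix(c(a1, a2, a3), nrow = 3L, byrow = TRUE)
  }
  root_child <- ord$kids[[1L]]
  fc <- f[[root_child]]
  per_char <- pmin(fc[1L, ], fc[2L, ] + 1, fc[3L, ] + 2)
  score <- sum(per_char)
  if (!want_labels) return(list(score = score))
  ## top-down backtrack; smallest optimal state on ties (unique for binary
  ## internal nodes, where the optimum is the componentwise meet)
  labels <- matrix(NA_integer_, n_nodes, m)
  labels[1L, ] <- 0L
  for (v in ord$preorder) {
    if (v == 1L) next
    s <- labels[parent[v], ]
    fv <- f[[v]]
    best <- rep(BIG_COST * 2, m)
    lab <- rep(NA_integer_, m)
    for (t in 2:0) {
      cost <- ifelse(t >= s, (t - s) + fv[t + 1L, ], BIG_COST * 2)
      take <- cost <= best
      best[take] <- cost[take]
      lab[take] <- t
    }
    labels[v, ] <- lab
  }
  list(score = score, labels = labels)
}

#' Infer all co-optimal maximum-parsimony clone trees
#'
#' Exhaustively searches rooted trees over the observed subclone genotypes
#' under the ordered irreversible model and returns every distinct clone
#' tree achieving the minimum total number of evolutionary changes. The
#' germline root is fixed; inferred ancestral subclones (unobserved
#' genotypes) appear only where they reduce the score; observed genotypes
#' may occupy internal positions. Trees are deduplicated by their edge
#' multiset of (parent genotype, child genotype) pairs and returned in a
#' deterministic canonical order.
#'
#' @param sc a [subclone_set()] (<= `max_subclones` subclones).
#' @param max_subclones practical search bound (default 9; (2k-3)!! rooted
#'   topologies are scored).
#' @return list of `clone_tree` objects, with attributes `score` (the
#'   parsimony score shared by all trees) and `n_topologies` scored.
#' @export
infer_parsimony_trees <- function(sc, max_subclones = 9L) {
  abort_if(!inherits(sc, "subclone_set"), "sc must be a subclone_set")
  k <- nrow(sc$genotypes)
  abort_if(k < 1L, "no subclones to place on a tree")
  abort_if(k > max_subclones,
           "search bound exceeded: ", k, " subclones > ", max_subclones)
  steps <- geno_to_steps(sc$genotypes, sc$markers)   # errors on reversals

  if (k == 1L) {
    parent <- c(NA_integer_, 1L)
    labels <- matrix(c(rep(0L, ncol(steps)), steps[1L, ]), nrow = 2L,
                     byrow = TRUE)
    tree <- build_clone_tree(parent, labels, sc)
    trees <- list(tree)
    attr(trees, "score") <- sum(steps[1L, ])
    attr(trees, "n_topologies") <- 1L
    return(trees)
  }

  topos <- enumerate_topologies(k)
  orders <- enumerate_topology_orders(k)
  leaf_f <- leaf_cost_matrices(steps)
  scores <- vapply(seq_along(topos), function(i)
    sankoff_topology(topos[[i]], steps, want_labels = FALSE,
                     ord = orders[[i]], leaf_f = leaf_f)$score, numeric(1))
  best <- min(scores)
  seen <- character(0)
  trees <- list()
  for (i in which(scores == best)) {
    fit <- sankoff_topology(topos[[i]], steps, want_labels = TRUE,
                            ord = orders[[i]])
    tree <- build_clone_tree(topos[[i]], fit$labels, sc)
    key <- attr(tree, "canonical_key")
    if (!key %in% seen) {
      seen <- c(seen, key)
      trees <- c(trees, list(tree))
    }
  }
  ord <- order(seen)
  trees <- trees[ord]
  attr(trees, "score") <- as.integer(best)
  attr(trees, "n_topologies") <- length(topos)
  trees
}

#' Parsimony score of a clone tree
#'
#' Total unit changes over all edges (each sequence-state increment and
#' each single-copy loss counts 1); equals the sum of branch lengths.
#' Errors if any edge implies a reversal.
#'
#' @param tree a `clone_tree`.
#' @return integer score.
#' @export
parsimony_score <- function(tree) {
  abort_if(!inherits(tree, "clone_tree"), "not a clone_tree")
  S <- geno_to_steps(tree$genotypes, tree$markers)
  total <- 0L
  for (i in seq_len(nrow(tree$edges))) {
    d <- S[tree$edges$child[i], ] - S[tree$edges$parent[i], ]
    abort_if(any(d < 0), "edge ", tree$edges$parent[i], " -> ",
             tree$edges$child[i], " implies a reversal")
    total <- total + sum(d)
  }
  as.integer(total)
}

#' Exhaustive brute-force minimum parsimony score (test oracle)
#'
#' Independently of [infer_parsimony_trees()], enumerates rooted binary
#' topologies by recursive leaf insertion and scores each by the
#' closed-form meet labelling (every internal node takes the componentwise
#' minimum of its children; optimal for irreversible unit-cost
#' characters). Intended as a small-instance oracle.
#'
#' @param sc a [subclone_set()] with at most `max_subclones` subclones.
#' @param max_subclones refusal bound (default 7).
#' @return integer global minimum score.
#' @export
brute_force_min_score <- function(sc, max_subclones = 7L) {
  abort_if(!inherits(sc, "subclone_set"), "sc must be a subclone_set")
  steps <- geno_to_steps(sc$genotypes, sc$markers)
  k <- nrow(steps)
  abort_if(k > max_subclones,
           "refusing brute force beyond ", max_subclones, " subclones")
  if (k == 1L) return(as.integer(sum(steps[1L, ])))

  score_tree <- function(node) {
    if (!is.list(node)) {
      return(list(lab = steps[node, ], cost = 0))
    }
    L <- score_tree(node[[1L]])
    R <- score_tree(node[[2L]])
    lab <- pmin(L$lab, R$lab)
    list(lab = lab,
         cost = L$cost + R$cost + sum(L$lab - lab) + sum(R$lab - lab))
  }
  trees <- bf_tree_shapes(k)
  best <- Inf
  for (t in trees) {
    st <- score_tree(t)
    best <- min(best, st$cost + sum(st$lab))   # + root edge from germline
  }
  as.integer(best)
}

## nested-list binary tree shapes over leaves 1..k (recursive insertion,
## independent of the main enumerator); cached per k
.bf_cache <- new.env(parent = emptyenv())

bf_tree_shapes <- function(k) {
  key <- as.character(k)
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  insert_everywhere <- function(tree, leaf) {
    res <- list(list(tree, leaf))          # join above the current root
    if (is.list(tree)) {
      for (side in 1:2) {
        for (sub in insert_everywhere(tree[[side]], leaf)) {
          nt <- tree
          nt[[side]] <- sub
          res <- c(res, list(nt))
        }
      }
    }
    res
  }
  trees <- list(1L)
  if (k >= 2L) for (j in 2:k)
    trees <- unlist(lapply(trees, insert_everywhere, leaf = j),
                    recursive = FALSE)
  .bf_cache[[key]] <- trees
  trees
}

#' Count independent origins per gene across co-optimal trees
#'
#' For each gene, counts the edges on which any marker of that gene
#' changes, takes the minimum over the supplied co-optimal trees, and
#' flags genes with two or more independent origins as reiterative
#' (parallel evolution).
#'
#' @param trees a list of `clone_tree` objects (as returned by
#'   [infer_parsimony_trees()]), or a single tree.
#' @return data.frame with `gene`, `n_origins`, `reiterative`.
#' @export
detect_reiterative_events <- function(trees) {
  if (inherits(trees, "clone_tree")) trees <- list(trees)
  abort_if(length(trees) == 0L, "empty tree set")
  markers <- trees[[1L]]$markers
  genes <- unique(markers$gene)
  per_tree <- sapply(trees, function(tree) {
    S <- geno_to_steps(tree$genotypes, tree$markers)
    counts <- setNames(integer(length(genes)), genes)
    for (i in seq_len(nrow(tree$edges))) {
      d <- S[tree$edges$child[i], ] - S[tree$edges$parent[i], ]
      hit_genes <- unique(markers$gene[d > 0])
      counts[hit_genes] <- counts[hit_genes] + 1L
    }
    counts
  })
  per_tree <- matrix(per_tree, nrow = length(genes),
                     dimnames = list(genes, NULL))
  n_origins <- apply(per_tree, 1L, min)
  data.frame(gene = genes, n_origins = as.integer(n_origins),
             reiterative = n_origins >= 2L, row.names = NULL,
             stringsAsFactors = FALSE)
}
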