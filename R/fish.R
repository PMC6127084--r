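## Multicolour interphase FISH: per-cell probe signal counts are collapsed
## into signal patterns (putative subclones) and ordered by lesion
## containment into an evolutionary diagram.
##
## Probe semantics: a fusion probe is encoded as the number of retained
## co-localised red-green signal pairs (a normal cell shows 2; a cell with
## the fusion, caused by an interstitial deletion, loses one red signal
## while retaining the green control, i.e. 1 intact pair); a locus
## copy-number probe is encoded as its signal count (2/1/0 copies).

#' Define FISH probes
#'
#' @param id probe ids (column names of the cell table).
#' @param type `"fusion"` (count of intact co-localised pairs) or
#'   `"cn"` (locus copy number).
#' @return data.frame with `id`, `type`.
#' @export
fish_probes <- function(id, type) {
  abort_if(!all(type %in% c("fusion", "cn")),
           "probe type must be 'fusion' or 'cn'")
  data.frame(id = as.character(id), type = rep_len(type, length(id)),
             stringsAsFactors = FALSE)
}

## probe states -> steps from normal (0 = no lesion); errors on gains
fish_steps <- function(states, probes) {
  S <- as.matrix(states)
  S <- matrix(2L - as.integer(S), nrow(S), ncol(S),
              dimnames = dimnames(states))
  abort_if(any(S < 0L),
           "signal counts above 2 imply gains, which the irreversible ",
           "containment model cannot order")
  abort_if(any(S > 2L), "signal counts must be >= 0")
  S
}

#' Tabulate FISH signal patterns
#'
#' Cells with identical per-probe state tuples merge into patterns; each
#' pattern's frequency is its percentage of all scored cells. Patterns
#' below `min_cells` are reported separately, so cell totals are
#' conserved.
#'
#' @param tbl data.frame: `cell_id` then one integer column per probe.
#' @param probes a [fish_probes()] table matching the columns.
#' @param min_cells minimum cells for a reported pattern.
#' @return An object of class `fish_patterns`: `patterns` (data.frame of
#'   probe states plus `pattern_id`, `count`, `pct`), `below_threshold`,
#'   `n_cells`, `probes`.
#' @export
tabulate_fish_patterns <- function(tbl, probes, min_cells = 1L) {
  abort_if(nrow(tbl) == 0L, "FISH cell table is empty")
  abort_if(!all(probes$id %in% names(tbl)),
           "cell table lacks columns for some probes")
  X <- as.matrix(tbl[, probes$id, drop = FALSE])
  abort_if(any(is.na(X)) || any(X < 0),
           "signal counts must be non-negative integers")
  keys <- apply(X, 1L, paste, collapse = ",")
  tab <- sort(table(keys), decreasing = TRUE)
  ord <- order(-as.integer(tab), names(tab))
  tab <- tab[ord]
  keep <- as.integer(tab) >= min_cells
  mk_df <- function(nms, counts) {
    if (!length(nms))
      return(cbind(as.data.frame(matrix(integer(0), 0, length(probes$id),
                                        dimnames = list(NULL, probes$id))),
                   data.frame(count = integer(0), pct = numeric(0))))
    st <- do.call(rbind, lapply(strsplit(nms, ","), as.integer))
    colnames(st) <- probes$id
    data.frame(st, count = as.integer(counts),
               pct = 100 * as.integer(counts) / nrow(tbl),
               stringsAsFactors = FALSE)
  }
  patterns <- mk_df(names(tab)[keep], tab[keep])
  if (nrow(patterns))
    patterns <- cbind(pattern_id = paste0("P", seq_len(nrow(patterns))),
                      patterns, stringsAsFactors = FALSE)
  below <- mk_df(names(tab)[!keep], tab[!keep])
  structure(list(patterns = patterns, below_threshold = below,
                 n_cells = nrow(tbl), probes = probes),
            class = "fish_patterns")
}

#' @export
print.fish_patterns <- function(x, ...) {
  cat(sprintf("fish_patterns: %d patterns over %d cells\n",
              nrow(x$patterns), x$n_cells))
  print(x$patterns, row.names = FALSE)
  invisible(x)
}

#' Order FISH patterns into a containment tree
#'
#' Pattern A is ancestral to pattern B iff every lesion of A is at most as
#' severe as B's (componentwise, in the irreversible model: pairs lost and
#' copies lost only increase). Each pattern is attached to its unique
#' maximal strictly-contained pattern; when several incomparable maximal
#' lower bounds exist the pattern is attached to their meet (componentwise
#' least severe common ancestor state), added as an inferred node if not
#' observed, and flagged ambiguous. A normal root (all probes at 2) is
#' added if absent. Patterns implying signal gains cannot be ordered and
#' raise an error.
#'
#' @param fp a [tabulate_fish_patterns()] result.
#' @param absorb_single_dropout if `TRUE`, a pattern differing from a
#'   >= 10x larger pattern by exactly one probe showing exactly one signal
#'   fewer (a plausible single hybridisation-failure event) is absorbed
#'   into the larger pattern before ordering. Default off.
#' @return A `clone_tree`-like object of class `fish_tree`: `nodes`
#'   (pattern states, counts, pct, `inferred`, `ambiguous`), `edges`
#'   (`parent`, `child`, `length` = lesion steps added), `steps` matrix.
#' @export
build_containment_tree <- function(fp, absorb_single_dropout = FALSE) {
  abort_if(!inherits(fp, "fish_patterns"), "fp must be fish_patterns")
  pat <- fp$patterns
  abort_if(nrow(pat) == 0L, "no patterns to order")
  probes <- fp$probes
  X <- as.matrix(pat[, probes$id, drop = FALSE])
  counts <- pat$count
  ids <- if ("pattern_id" %in% names(pat)) pat$pattern_id
         else paste0("P", seq_len(nrow(X)))

  if (absorb_single_dropout && nrow(pat) > 1L) {
    keep <- rep(TRUE, nrow(pat))
    for (i in seq_len(nrow(pat))) {
      for (j in seq_len(nrow(pat))) {
        if (i == j || !keep[i] || !keep[j]) next
        d <- X[j, ] - X[i, ]     # i has fewer signals than j at one probe
        if (sum(d != 0) == 1L && sum(d) == 1L &&
            counts[j] >= 10L * counts[i]) {
          counts[j] <- counts[j] + counts[i]
          keep[i] <- FALSE
          break
        }
      }
    }
    X <- X[keep, , drop = FALSE]
    counts <- counts[keep]
    ids <- ids[keep]
  }

  S <- fish_steps(X, probes)               # errors on gains
  normal_row <- which(apply(S, 1L, function(s) all(s == 0L)))
  if (length(normal_row)) {
    ids[normal_row[1L]] <- "N"
  } else {
    S <- rbind(rep(0L, ncol(S)), S)
    counts <- c(0L, counts)
    ids <- c("N", ids)
  }
  inferred <- ids != "N" & counts == 0L
  rownames(S) <- ids

  leq <- function(a, b) all(a <= b)        # a ancestral-or-equal to b
  lt <- function(a, b) leq(a, b) && any(a < b)

  ## close the node set under the meets needed to host ambiguous patterns
  repeat {
    added <- FALSE
    for (r in which(ids != "N")) {
      lower <- which(vapply(seq_len(nrow(S)), function(q)
        lt(S[q, ], S[r, ]), logical(1)))
      maximal <- lower[vapply(lower, function(q)
        !any(vapply(lower, function(z) lt(S[q, ], S[z, ]), logical(1))),
        logical(1))]
      if (length(maximal) > 1L) {
        meet <- apply(S[maximal, , drop = FALSE], 2L, min)
        if (!any(vapply(seq_len(nrow(S)), function(q)
          all(S[q, ] == meet), logical(1)))) {
          newid <- paste0("M", sum(grepl("^M", ids)) + 1L)
          S <- rbind(S, meet)
          rownames(S)[nrow(S)] <- newid
          ids <- c(ids, newid)
          counts <- c(counts, 0L)
          inferred <- c(inferred, TRUE)
          added <- TRUE
        }
      }
    }
    if (!added) break
  }

  ## parent: unique maximal strictly-contained node, or (ambiguous) the
  ## meet of the incomparable maximal lower bounds
  parent <- setNames(rep(NA_character_, nrow(S)), ids)
  ambiguous <- setNames(rep(FALSE, nrow(S)), ids)
  for (r in which(ids != "N")) {
    lower <- which(vapply(seq_len(nrow(S)), function(q)
      lt(S[q, ], S[r, ]), logical(1)))
    maximal <- lower[vapply(lower, function(q)
      !any(vapply(lower, function(z) lt(S[q, ], S[z, ]), logical(1))),
      logical(1))]
    if (length(maximal) == 1L) {
      parent[r] <- ids[maximal]
    } else {
      meet <- apply(S[maximal, , drop = FALSE], 2L, min)
      hit <- which(vapply(seq_len(nrow(S)), function(q)
        all(S[q, ] == meet), logical(1)))[1L]
      parent[r] <- ids[hit]
      ambiguous[r] <- TRUE
    }
  }

  ord_rows <- order(rowSums(S), ids)
  S <- S[ord_rows, , drop = FALSE]
  counts <- counts[ord_rows]
  ids <- ids[ord_rows]
  parent <- parent[ord_rows]
  ambiguous <- ambiguous[ord_rows]
  inferred <- inferred[ord_rows]

  child_rows <- which(ids != "N")
  edges <- data.frame(parent = unname(parent[child_rows]),
                      child = ids[child_rows],
                      length = vapply(child_rows, function(q)
                        sum(S[q, ] - S[match(parent[q], ids), ]),
                        numeric(1)),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  nodes <- data.frame(id = ids,
                      as.data.frame(matrix(2L - S, nrow(S),
                                           dimnames = list(NULL, probes$id))),
                      count = as.integer(counts),
                      pct = 100 * counts / max(1L, fp$n_cells),
                      inferred = unname(inferred),
                      ambiguous = unname(ambiguous),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, steps = S, probes = probes,
                 root = "N", n_cells = fp$n_cells),
            class = "fish_tree")
}

#' @export
print.fish_tree <- function(x, ...) {
  cat(sprintf("fish_tree: %d nodes (%d inferred)\n", nrow(x$nodes),
              sum(x$nodes$inferred)))
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -> %s [%d lesion step%s]\n", x$edges$parent[i],
                x$edges$child[i], x$edges$length[i],
                if (x$edges$length[i] == 1) "" else "s"))
  invisible(x)
}
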