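## Collapse per-cell genotypes into subclones (cells sharing one genotype
## over the tracked panel).

#' Collapse cells into subclones
#'
#' Identical complete genotype rows merge into subclones; genotypes seen
#' in fewer than `min_cells` cells are reported separately as below the
#' level of reliable detection (not silently dropped). Cells with missing
#' calls are assigned to a subclone when exactly one subclone matches all
#' their observed markers, otherwise counted as unassigned. Counts
#' reconcile: assigned + unassigned + below-threshold = input cells.
#'
#' Allelic dropout moves calls in a known direction (a heterozygous
#' mutation reads wild type; a two-copy locus reads one copy), so a small
#' genotype class differing from a much larger class by exactly one
#' marker, shifted one step in the dropout direction, is most plausibly
#' that larger clone seen through dropout. `absorb_dropout_classes`
#' merges such satellite classes into their parent class before
#' thresholding; safe whenever true subclones differ by at least two
#' markers, as dropout then never bridges two real clones.
#'
#' @param gm a [genotype_matrix()].
#' @param min_cells minimum cells for a genotype to count as a detected
#'   subclone (>= 1).
#' @param na_policy `"assign_unique"` (default) assigns NA-containing rows
#'   to a uniquely compatible subclone; `"unassigned"` never assigns them.
#' @param absorb_dropout_classes merge single-dropout satellite classes
#'   into a dominating class before thresholding (default `FALSE`).
#' @param absorb_ratio minimum size ratio (larger/smaller) for
#'   absorption (default 3).
#' @return An object of class `subclone_set`: `genotypes` (subclones x
#'   markers, raw states; rownames `C1`, `C2`, ... by decreasing size),
#'   `counts`, `frequencies` (count / total input cells), `n_total`,
#'   `n_unassigned`, `below_threshold` (data.frame of genotype keys and
#'   counts), `markers`.
#' @export
collapse_subclones <- function(gm, min_cells = 2L,
                               na_policy = c("assign_unique", "unassigned"),
                               absorb_dropout_classes = FALSE,
                               absorb_ratio = 3) {
  na_policy <- match.arg(na_policy)
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  G <- gm$genotypes
  abort_if(nrow(G) == 0L, "genotype matrix is empty")
  abort_if(!is_count(min_cells), "min_cells must be a positive integer")

  complete <- !apply(is.na(G), 1L, any)
  keys <- apply(G, 1L, geno_key)
  tab <- sort(table(keys[complete]), decreasing = TRUE)

  if (absorb_dropout_classes && length(tab) > 1L) {
    tab <- absorb_dropout(tab, gm$markers, absorb_ratio)
  }
  detected <- names(tab)[tab >= min_cells]
  ## deterministic order: by count desc, then genotype key
  ord <- order(-as.integer(tab[detected]), detected)
  detected <- detected[ord]
  below <- setdiff(names(tab), detected)

  k <- length(detected)
  first_row <- match(detected, keys)
  sub_geno <- G[first_row, , drop = FALSE]
  rownames(sub_geno) <- if (k) paste0("C", seq_len(k)) else character(0)
  counts <- as.integer(tab[detected])

  n_unassigned <- 0L
  na_rows <- which(!complete)
  if (length(na_rows) && na_policy == "assign_unique" && k > 0L) {
    for (i in na_rows) {
      obs <- !is.na(G[i, ])
      hit <- which(apply(sub_geno, 1L, function(s)
        all(s[obs] == G[i, obs])))
      if (length(hit) == 1L) counts[hit] <- counts[hit] + 1L
      else n_unassigned <- n_unassigned + 1L
    }
  } else {
    n_unassigned <- length(na_rows)
  }

  below_df <- data.frame(genotype_key = below,
                         count = as.integer(tab[below]),
                         stringsAsFactors = FALSE)
  out <- structure(list(genotypes = sub_geno,
                        counts = setNames(counts, rownames(sub_geno)),
                        frequencies = setNames(counts / nrow(G),
                                               rownames(sub_geno)),
                        n_total = nrow(G),
                        n_unassigned = n_unassigned,
                        below_threshold = below_df,
                        markers = gm$markers),
                   class = "subclone_set")
  stopifnot(sum(out$counts) + out$n_unassigned + sum(below_df$count) ==
              out$n_total)
  out
}

## Merge genotype classes that look like single-dropout satellites of a
## much larger class. Dropout direction: sequence state one lower (mutant
## allele lost), or copy number one-two lower (copies lost at capture).
## Applied smallest-class-first until stable.
absorb_dropout <- function(tab, markers, absorb_ratio) {
  parse_key <- function(k) as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
  repeat {
    keys <- names(tab)
    counts <- as.integer(tab)
    genos <- lapply(keys, parse_key)
    merged <- FALSE
    for (i in order(counts)) {
      for (j in order(-counts)) {
        if (i == j) next
        if (counts[j] < absorb_ratio * counts[i]) break
        d <- genos[[i]] - genos[[j]]
        diff_at <- which(d != 0L)
        if (length(diff_at) != 1L) next
        ## dropout lowers the raw state for both families: a het mutation
        ## reads wt, a retained locus loses observed copies
        if (!d[diff_at] %in% c(-1L, -2L)) next
        counts[j] <- counts[j] + counts[i]
        counts[i] <- 0L
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
    keep <- counts > 0L
    tab <- sort(stats::setNames(counts[keep], keys[keep]), decreasing = TRUE)
  }
  tab
}

#' Construct a subclone set directly from genotypes
#'
#' Useful for encoding published subclone genotypes (e.g. transcribed from
#' a figure) without per-cell data.
#'
#' @param genotypes subclones x markers matrix of raw states.
#' @param markers the [marker_table()].
#' @param counts cell counts per subclone (default 1 each).
#' @return A `subclone_set`.
#' @export
subclone_set <- function(genotypes, markers, counts = NULL) {
  genotypes <- as.matrix(genotypes)
  abort_if(ncol(genotypes) != nrow(markers),
           "genotype columns do not match the marker panel")
  colnames(genotypes) <- markers$id
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("C", seq_len(nrow(genotypes)))
  keys <- apply(genotypes, 1L, geno_key)
  abort_if(anyDuplicated(keys) > 0L, "subclone genotypes must be distinct")
  invisible(geno_to_steps(genotypes, markers))
  if (is.null(counts)) counts <- rep(1L, nrow(genotypes))
  structure(list(genotypes = genotypes,
                 counts = setNames(as.integer(counts), rownames(genotypes)),
                 frequencies = setNames(counts / sum(counts),
                                        rownames(genotypes)),
                 n_total = sum(counts),
                 n_unassigned = 0L,
                 below_threshold = data.frame(genotype_key = character(0),
                                              count = integer(0)),
                 markers = markers),
            class = "subclone_set")
}

#' @export
print.subclone_set <- function(x, ...) {
  cat(sprintf("subclone_set: %d subclones over %d markers, %d cells (%d unassigned, %d below threshold)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$n_total,
              x$n_unassigned, sum(x$below_threshold$count)))
  invisible(x)
}
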