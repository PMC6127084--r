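## File formats. Missing values are serialised as the literal "NA" in all
## TSVs; FASTA is normalised to uppercase on read; trees are written as
## Newick (topology + branch lengths + support) with a JSON sidecar
## carrying per-node genotypes, counts, inferred flags and xenograft
## read-out status.

#' Write / read a genotype matrix as TSV
#'
#' Columns: `cell_id` then one column per marker; `NA` is written
#' literally.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(cell_id = rownames(gm$genotypes) %||% character(0),
                   gm$genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @param markers the [marker_table()] the file was written against.
#' @export
read_genotype_tsv <- function(path, markers) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  abort_if(!"cell_id" %in% names(df), "missing cell_id column in ", path)
  missing <- setdiff(markers$id, names(df))
  abort_if(length(missing) > 0L,
           "genotype TSV lacks marker columns: ",
           paste(missing, collapse = ", "))
  G <- as.matrix(df[, markers$id, drop = FALSE])
  mode(G) <- "integer"
  rownames(G) <- df$cell_id
  genotype_matrix(G, markers)
}

#' Write / read a Ct matrix as TSV
#'
#' Columns: `cell_id` then `<assay>__rep<k>`.
#'
#' @param ct Ct data.frame ([simulate_ct_readout()]).
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_ct_tsv <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  abort_if(!"cell_id" %in% names(df), "missing cell_id column in ", path)
  abort_if(!any(grepl("__rep[0-9]+$", names(df))),
           "no assay replicate columns (<assay>__rep<k>) in ", path)
  df
}

#' Write sequences as FASTA (with optional coordinate sidecar)
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @param path FASTA path.
#' @param info optional data.frame of planted-motif coordinates
#'   ([make_breakpoint_sequences()]); written as `<path>.offsets.tsv`
#'   (0-based half-open, strand + or -).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, info = NULL) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  if (!is.null(info))
    utils::write.table(info, paste0(path, ".offsets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read FASTA, normalising to uppercase
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] (uppercase).
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  Biostrings::DNAStringSet(toupper(as.character(s)))
}

#' Write a clone tree as Newick plus JSON sidecar
#'
#' @param tree a `clone_tree`.
#' @param path output path without extension; writes `<path>.nwk` and
#'   `<path>.json`.
#' @param t_status optional named logical: xenograft read-out per node id.
#' @return paths, invisibly.
#' @export
write_clone_tree <- function(tree, path, t_status = NULL) {
  nwk <- paste0(path, ".nwk")
  writeLines(clone_tree_newick(tree), nwk)
  nodes <- tree$nodes
  if (!is.null(t_status)) {
    nodes$t_status <- unname(t_status[nodes$id])
  }
  payload <- list(
    nodes = lapply(seq_len(nrow(nodes)), function(i) {
      x <- as.list(nodes[i, , drop = FALSE])
      x$genotype <- as.list(setNames(as.integer(tree$genotypes[nodes$id[i], ]),
                                     tree$markers$id))
      x
    }),
    edges = tree$edges,
    markers = tree$markers,
    parsimony_score = parsimony_score(tree))
  jsonlite::write_json(payload, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(nwk, paste0(path, ".json")))
}

#' Read a clone-tree Newick file into an ape phylo object
#'
#' Node labels carry the subclone ids with bootstrap support after `#`.
#'
#' @param path Newick file.
#' @return An `ape::phylo` (singleton nodes preserved).
#' @export
read_clone_tree_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  ape::read.tree(text = txt)
}
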