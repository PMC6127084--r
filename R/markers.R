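## Marker definitions and the ordered irreversible state model.
##
## Two marker families are tracked per cell:
##   * sequence markers (fusion, snv, indel): states 0 = wild type,
##     1 = heterozygous, 2 = homozygous; states only ever increase.
##   * copy-number markers (cn_loss): copies 2, 1, 0; copies only ever
##     decrease (no gains are modelled).
## Internally both are mapped onto a common "steps from germline" scale
## (0, 1, 2) on which every evolutionary change is a unit increment.

MARKER_CLASSES <- c("fusion", "snv", "indel", "cn_loss")

#' Define a marker panel
#'
#' A marker is one tracked lesion: a patient-specific fusion, an SNV or
#' indel (with zygosity), or a locus copy-number loss. Several markers may
#' belong to the same gene (reiterative, i.e. independent parallel hits).
#'
#' @param id character vector of unique marker ids.
#' @param class character vector, one of `"fusion"`, `"snv"`, `"indel"`,
#'   `"cn_loss"`.
#' @param gene gene symbol per marker; defaults to `id`.
#' @param steps number of unit changes the lesion contributes when it is
#'   acquired: 1 (heterozygous hit / single copy loss) or 2 (homozygous
#'   hit / bi-allelic loss). Defaults to 1.
#' @return A `data.frame` with columns `id`, `gene`, `class`, `steps`.
#' @examples
#' marker_table(
#'   id    = c("STIL_TAL1", "CDKN2A", "PTEN_i1"),
#'   class = c("fusion", "cn_loss", "indel"),
#'   gene  = c("STIL_TAL1", "CDKN2A", "PTEN"),
#'   steps = c(1, 2, 1))
#' @export
marker_table <- function(id, class, gene = id, steps = 1L) {
  abort_if(anyDuplicated(id) > 0L, "marker ids must be unique")
  abort_if(!all(class %in% MARKER_CLASSES),
           "marker class must be one of: ", paste(MARKER_CLASSES, collapse = ", "))
  steps <- as.integer(rep_len(steps, length(id)))
  abort_if(!all(steps %in% 1:2), "marker steps must be 1 or 2")
  data.frame(id = as.character(id), gene = rep_len(as.character(gene), length(id)),
             class = as.character(class), steps = steps,
             stringsAsFactors = FALSE)
}

is_cn_marker <- function(markers) markers$class == "cn_loss"

#' Germline genotype for a marker panel
#'
#' @param markers a [marker_table()].
#' @return Named integer vector: 0 for sequence markers, 2 (copies) for
#'   copy-number markers.
#' @export
germline_genotype <- function(markers) {
  g <- ifelse(is_cn_marker(markers), 2L, 0L)
  names(g) <- markers$id
  g
}

## raw states -> steps-from-germline (0..2); validates state ranges.
## G: matrix or vector in raw states (seq 0/1/2; cn copies 2/1/0).
geno_to_steps <- function(G, markers) {
  vec <- is.null(dim(G))
  if (vec) G <- matrix(G, nrow = 1L, dimnames = list(NULL, names(G)))
  abort_if(ncol(G) != nrow(markers), "genotype width does not match marker panel")
  cn <- is_cn_marker(markers)
  S <- G
  S[, cn] <- 2L - G[, cn, drop = FALSE]
  bad <- !is.na(S) & (S < 0L | S > 2L)
  abort_if(any(bad),
           "invalid marker states (sequence states must be 0..2, copies 0..2; ",
           "copy gains are not representable in the irreversible model)")
  if (vec) S[1L, ] else S
}

steps_to_geno <- function(S, markers) {
  vec <- is.null(dim(S))
  if (vec) S <- matrix(S, nrow = 1L, dimnames = list(NULL, names(S)))
  cn <- is_cn_marker(markers)
  G <- S
  G[, cn] <- 2L - S[, cn, drop = FALSE]
  if (vec) G[1L, ] else G
}

## human-readable description of the change of marker j from raw a to raw b
describe_change <- function(marker, a, b) {
  if (marker$class == "cn_loss") {
    sprintf("%s:%d->%d copies", marker$id, a, b)
  } else {
    lab <- c("wt", "het", "hom")
    sprintf("%s:%s->%s", marker$id, lab[a + 1L], lab[b + 1L])
  }
}
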