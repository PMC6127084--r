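## Genotype calling from duplicated single-cell qPCR Ct matrices.
##
## Calling rules (all configurable):
##   * a well "amplifies" if its Ct is below ct_max and not the sentinel;
##   * mutation-specific assay: both duplicates amplify -> positive, both
##     fail -> negative, discordant -> missing (conservative against
##     amplification artifacts);
##   * copy number: mean delta-Ct (assay - control) against two increasing
##     band cutpoints separating 2/1/0 copies; both assay wells dark with
##     amplifying controls -> 0 copies; control failure -> NA;
##   * homozygosity of a sequence marker requires a paired wild-type-allele
##     assay that is negative; otherwise zygosity is capped at heterozygous.

amplifies <- function(ct, ct_max, sentinel) {
  !is.na(ct) & ct != sentinel & ct < ct_max
}

#' Call one duplicated mutation-specific assay
#'
#' @param replicate_cts numeric vector of the duplicate Ct values
#'   (sentinel = no amplification).
#' @param ct_max maximum Ct accepted as amplification (cycles).
#' @param sentinel the no-amplification sentinel value.
#' @return `"positive"`, `"negative"`, or `"missing"` (duplicates
#'   discordant).
#' @export
call_mutation_assay <- function(replicate_cts, ct_max = 38, sentinel = 40) {
  amp <- amplifies(replicate_cts, ct_max, sentinel)
  if (all(amp)) "positive" else if (!any(amp)) "negative" else "missing"
}

#' Call copy number from a duplicated assay against a control assay
#'
#' @param assay_cts duplicate Ct values of the copy-number assay.
#' @param control_cts duplicate Ct values of the reference control assay.
#' @param bands two increasing delta-Ct cutpoints separating 2/1/0 copies;
#'   mean delta-Ct below `bands[1]` calls 2 copies, between the cuts 1
#'   copy, at or above `bands[2]` 0 copies.
#' @param ct_max,sentinel as in [call_mutation_assay()].
#' @return Integer copies 2, 1 or 0, or `NA` (control failure or
#'   discordant assay duplicates).
#' @export
call_copy_number <- function(assay_cts, control_cts, bands = c(0.5, 1.5),
                             ct_max = 38, sentinel = 40) {
  abort_if(length(bands) != 2L || diff(bands) <= 0,
           "bands must be two increasing delta-Ct cutpoints")
  ctrl_amp <- amplifies(control_cts, ct_max, sentinel)
  if (!any(ctrl_amp)) return(NA_integer_)
  amp <- amplifies(assay_cts, ct_max, sentinel)
  if (!any(amp)) return(0L)
  if (!all(amp)) return(NA_integer_)      # discordant duplicates
  dct <- mean(assay_cts) - mean(control_cts[ctrl_amp])
  if (dct < bands[1L]) 2L else if (dct < bands[2L]) 1L else 0L
}

#' Build a per-cell genotype matrix from a Ct matrix
#'
#' Applies [call_mutation_assay()] and [call_copy_number()] marker-wise.
#' A positive mutation-specific call gives state 1 (het) unless the panel
#' carries a paired wild-type-allele assay that calls negative, in which
#' case state 2 (hom). Per-cell QC records whether every control assay
#' amplified and how many marker calls are missing.
#'
#' @param ct data.frame as written by [simulate_ct_readout()] /
#'   [read_ct_tsv()]: `cell_id` then `<assay>__rep<k>` columns.
#' @param markers the [marker_table()].
#' @param panel the assay panel ([make_assay_panel()]).
#' @param ct_max,bands,sentinel calling thresholds.
#' @return An object of class `genotype_matrix`: list with `genotypes`
#'   (cells x markers, raw states, `NA` = missing), `markers`, and `qc`
#'   (data.frame `cell_id`, `controls_passed`, `n_missing`,
#'   `frac_missing`).
#' @export
build_genotype_matrix <- function(ct, markers, panel, ct_max = 38,
                                  bands = c(0.5, 1.5), sentinel = 40) {
  validate_panel(panel, markers)
  abort_if(!"cell_id" %in% names(ct), "Ct matrix must have a cell_id column")
  rep_cols <- function(assay) {
    cols <- sprintf("%s__rep%d", assay, 1:2)
    abort_if(!all(cols %in% names(ct)),
             "Ct matrix is missing duplicate columns for assay ", assay)
    as.matrix(ct[, cols])
  }
  n <- nrow(ct)
  G <- matrix(NA_integer_, n, nrow(markers),
              dimnames = list(ct$cell_id, markers$id))

  ctrl_ids <- panel$assay_id[panel$class == "control"]
  ctrl_ct <- lapply(ctrl_ids, rep_cols)
  controls_passed <- rep(TRUE, n)
  for (cc in ctrl_ct)
    controls_passed <- controls_passed &
      apply(cc, 1L, function(x) any(amplifies(x, ct_max, sentinel)))

  for (j in seq_len(nrow(markers))) {
    mk <- markers[j, ]
    if (mk$class == "cn_loss") {
      a <- panel[panel$marker_id == mk$id & panel$class == "copy_number", ]
      acts <- rep_cols(a$assay_id)
      ccts <- rep_cols(a$control_assay)
      G[, j] <- vapply(seq_len(n), function(i)
        call_copy_number(acts[i, ], ccts[i, ], bands, ct_max, sentinel),
        integer(1))
    } else {
      a <- panel[panel$marker_id == mk$id & panel$class == "mutation_specific", ]
      mcts <- rep_cols(a$assay_id)
      w <- panel[panel$marker_id == mk$id & panel$class == "wt_allele", ]
      wcts <- if (nrow(w)) rep_cols(w$assay_id) else NULL
      G[, j] <- vapply(seq_len(n), function(i) {
        call <- call_mutation_assay(mcts[i, ], ct_max, sentinel)
        if (call == "missing") return(NA_integer_)
        if (call == "negative") return(0L)
        if (!is.null(wcts) &&
            call_mutation_assay(wcts[i, ], ct_max, sentinel) == "negative")
          return(2L)
        1L
      }, integer(1))
    }
  }
  G[!controls_passed, ] <- NA_integer_
  n_missing <- rowSums(is.na(G))
  genotype_matrix(G, markers,
                  qc = data.frame(cell_id = ct$cell_id,
                                  controls_passed = controls_passed,
                                  n_missing = n_missing,
                                  frac_missing = n_missing / nrow(markers),
                                  stringsAsFactors = FALSE))
}

#' Construct a genotype matrix object
#'
#' @param genotypes cells x markers integer matrix of raw states (sequence
#'   markers 0/1/2, copy-number markers copies 2/1/0, `NA` = missing) with
#'   cell ids as rownames.
#' @param markers the [marker_table()].
#' @param qc optional per-cell QC data.frame; defaults to all passing.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, markers, qc = NULL) {
  genotypes <- as.matrix(genotypes)
  abort_if(ncol(genotypes) != nrow(markers),
           "genotype columns do not match the marker panel")
  colnames(genotypes) <- markers$id
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("cell_%04d", seq_len(nrow(genotypes)))
  ## validate state ranges (also rejects copy gains)
  invisible(geno_to_steps(genotypes, markers))
  if (is.null(qc)) {
    n_missing <- rowSums(is.na(genotypes))
    qc <- data.frame(cell_id = rownames(genotypes),
                     controls_passed = rep(TRUE, nrow(genotypes)),
                     n_missing = n_missing,
                     frac_missing = n_missing / nrow(markers),
                     stringsAsFactors = FALSE)
  }
  structure(list(genotypes = genotypes, markers = markers, qc = qc),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d cells x %d markers (%d calls missing)\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(is.na(x$genotypes))))
  invisible(x)
}

#' Remove low-quality cells from a genotype matrix
#'
#' Cells failing controls or exceeding the missing-call fraction are
#' removed; the report reconciles exactly (kept + removed = input).
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_frac maximum tolerated fraction of missing marker
#'   calls per cell, in \[0,1\].
#' @return list with `gm` (filtered) and `report` (counts per removal
#'   reason).
#' @export
qc_filter_cells <- function(gm, max_missing_frac = 0.3) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  abort_if(max_missing_frac < 0 || max_missing_frac > 1,
           "max_missing_frac must be in [0,1]")
  qc <- gm$qc
  fail_ctrl <- !qc$controls_passed
  fail_miss <- !fail_ctrl & qc$frac_missing > max_missing_frac
  keep <- !fail_ctrl & !fail_miss
  out <- genotype_matrix(gm$genotypes[keep, , drop = FALSE], gm$markers,
                         qc = qc[keep, , drop = FALSE])
  list(gm = out,
       report = list(n_input = nrow(qc), n_kept = sum(keep),
                     n_removed_control_failure = sum(fail_ctrl),
                     n_removed_missing = sum(fail_miss)))
}
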