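## Cohort-level driver-frequency summaries and diagnosis-versus-xenograft
## compartment comparison.

COHORT_STATUSES <- c("loss", "gain", "mutation", "wt")

#' Read a cohort driver-status table
#'
#' CSV with a `sample_id` column and one column per driver; cell values
#' are `loss`, `gain`, `mutation`, or `wt`.
#'
#' @param path CSV file path.
#' @return data.frame (one row per sample).
#' @export
read_cohort_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!"sample_id" %in% names(tbl),
           "cohort table must have a sample_id column")
  abort_if(anyDuplicated(tbl$sample_id) > 0L, "duplicated sample ids")
  vals <- unlist(tbl[setdiff(names(tbl), "sample_id")])
  abort_if(!all(vals %in% COHORT_STATUSES),
           "cohort statuses must be one of: ",
           paste(COHORT_STATUSES, collapse = ", "))
  tbl
}

#' Percentage of cohort samples satisfying a driver rule
#'
#' The rule is a one-sided formula over the table's columns, e.g.
#' `~ PTEN_exon7 == "mutation" | PTEN_cn == "loss"`. The exact numerator
#' and denominator are always reported alongside the percentage.
#'
#' @param tbl cohort table ([read_cohort_table()]).
#' @param rule one-sided formula over driver columns.
#' @param name label for the rule.
#' @return list with `name`, `percent`, `numerator`, `denominator`.
#' @export
driver_frequency <- function(tbl, rule, name = deparse(rule[[2]])) {
  abort_if(!inherits(rule, "formula") || length(rule) != 2L,
           "rule must be a one-sided formula")
  vars <- all.vars(rule)
  unknown <- setdiff(vars, names(tbl))
  abort_if(length(unknown) > 0L,
           "rule references unknown columns: ",
           paste(unknown, collapse = ", "))
  hit <- eval(rule[[2]], envir = tbl, enclos = environment(rule))
  abort_if(!is.logical(hit) || length(hit) != nrow(tbl),
           "rule must evaluate to one logical per sample")
  num <- sum(hit, na.rm = TRUE)
  list(name = name, percent = 100 * num / nrow(tbl),
       numerator = num, denominator = nrow(tbl))
}

#' Built-in driver rules for the shipped cohort table
#'
#' `rule_pten_inactivation` combines PTEN exon 7 mutation with PTEN copy
#' number loss; `rule_9p_loss` and `rule_6q_loss` are plain copy-number
#' loss rules.
#'
#' @name driver_rules
#' @export
rule_pten_inactivation <- ~ PTEN_exon7 == "mutation" | PTEN_cn == "loss"

#' @rdname driver_rules
#' @export
rule_9p_loss <- ~ CDKN2A_9p == "loss"

#' @rdname driver_rules
#' @export
rule_6q_loss <- ~ del_6q == "loss"

#' Path of the shipped synthetic cohort table
#'
#' A synthetic 20-sample stand-in for a published driver-status grid:
#' constructed to be consistent with the cohort-level frequencies and
#' per-sample driver statements the study reports (it is not a transcription
#' of the original table, which is only available as a figure).
#'
#' @return file path of the CSV.
#' @export
cohort_table_path <- function() {
  system.file("extdata", "cohort_table1_synthetic.csv",
              package = "sclonetree", mustWork = TRUE)
}

## NA-tolerant genotype match: equal on every marker observed in both
match_genotypes <- function(a, b, policy) {
  if (policy == "exact") return(!anyNA(a) && !anyNA(b) && all(a == b))
  obs <- !is.na(a) & !is.na(b)
  all(a[obs] == b[obs])
}

#' Compare diagnostic and xenograft subclone compartments
#'
#' A diagnostic subclone "reads out" in the xenograft (T-status, i.e.
#' evidence of leukaemia-propagating activity) iff some xenograft subclone
#' matches its genotype under `match_policy`. Frequency shifts are
#' reported per matched subclone; xenograft-only genotypes are flagged as
#' emergent. Swapping the two compartments swaps the emergent and extinct
#' labels (detection symmetry).
#'
#' @param diag a [subclone_set()] from the diagnostic sample.
#' @param xeno a [subclone_set()] from the xenograft, genotyped on the
#'   same marker panel.
#' @param match_policy `"na_tolerant"` (default: equality on co-observed
#'   markers) or `"exact"`.
#' @return An object of class `compartment_comparison`: `subclones`
#'   (data.frame: diagnostic id, diagnostic and xenograft frequencies,
#'   `t_status`, `freq_shift`), `emergent` (xenograft-only subclone ids),
#'   `extinct` (diagnostic subclones without read-out).
#' @export
compare_compartments <- function(diag, xeno,
                                 match_policy = c("na_tolerant", "exact")) {
  match_policy <- match.arg(match_policy)
  abort_if(!inherits(diag, "subclone_set") || !inherits(xeno, "subclone_set"),
           "both compartments must be subclone_sets")
  abort_if(!identical(diag$markers$id, xeno$markers$id),
           "compartments are genotyped on different marker panels")
  nd <- nrow(diag$genotypes)
  nx <- nrow(xeno$genotypes)
  match_of <- rep(NA_integer_, nd)
  for (i in seq_len(nd)) {
    hits <- which(vapply(seq_len(nx), function(j)
      match_genotypes(diag$genotypes[i, ], xeno$genotypes[j, ],
                      match_policy), logical(1)))
    if (length(hits)) match_of[i] <- hits[1L]
  }
  xeno_matched <- stats::na.omit(match_of)
  subclones <- data.frame(
    id = rownames(diag$genotypes),
    diagnostic_freq = as.numeric(diag$frequencies),
    xenograft_freq = ifelse(is.na(match_of), 0,
                            xeno$frequencies[match_of]),
    t_status = !is.na(match_of),
    stringsAsFactors = FALSE)
  subclones$freq_shift <- subclones$xenograft_freq - subclones$diagnostic_freq
  structure(list(
    subclones = subclones,
    emergent = setdiff(rownames(xeno$genotypes),
                       rownames(xeno$genotypes)[xeno_matched]),
    extinct = subclones$id[!subclones$t_status],
    match_policy = match_policy), class = "compartment_comparison")
}

#' @export
print.compartment_comparison <- function(x, ...) {
  cat(sprintf("compartment_comparison (%s): %d/%d diagnostic subclones read out\n",
              x$match_policy, sum(x$subclones$t_status), nrow(x$subclones)))
  print(x$subclones, row.names = FALSE)
  if (length(x$emergent))
    cat("emergent in xenograft:", paste(x$emergent, collapse = ", "), "\n")
  invisible(x)
}

#' Zygosity fractions of a sequence marker within a cell subset
#'
#' Proportions of wild-type, heterozygous and homozygous cells over the
#' non-missing calls (they sum to 1); the number of missing calls is
#' reported separately.
#'
#' @param gm a [genotype_matrix()].
#' @param marker id of a sequence marker.
#' @param cells optional character vector of cell ids to restrict to
#'   (e.g. the members of one subclone).
#' @return named numeric vector `c(wt=, het=, hom=)` with attribute
#'   `n_na`.
#' @export
zygosity_fractions <- function(gm, marker, cells = NULL) {
  abort_if(!inherits(gm, "genotype_matrix"), "gm must be a genotype_matrix")
  abort_if(!marker %in% gm$markers$id, "unknown marker: ", marker)
  abort_if(gm$markers$class[gm$markers$id == marker] == "cn_loss",
           "zygosity fractions apply to sequence markers only")
  v <- gm$genotypes[, marker]
  if (!is.null(cells)) v <- v[rownames(gm$genotypes) %in% cells]
  abort_if(length(v) == 0L, "no cells selected")
  n_na <- sum(is.na(v))
  v <- v[!is.na(v)]
  abort_if(length(v) == 0L,
           "all selected cells have a missing call for marker ", marker)
  out <- c(wt = mean(v == 0L), het = mean(v == 1L), hom = mean(v == 2L))
  attr(out, "n_na") <- n_na
  out
}
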