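## Synthetic-data generator: clonal ground truths, single-cell sampling,
## qPCR Ct readout with allelic dropout, xenograft bottlenecks, and
## breakpoint sequences with or without planted RSS motifs.

#' Noise model for simulated single-cell qPCR
#'
#' Allelic dropout (ADO) is applied once per allele per cell, before any
#' well is simulated: it models loss of template at lysis/capture, so both
#' duplicate wells of an assay see the same surviving alleles. Amplification
#' failure is an independent per-well event. Copy-number assays emit
#' `ct_baseline + ct_per_copy_shift * (2 - surviving copies)` plus Gaussian
#' noise, the standard delta-Ct behaviour of one cycle per template halving;
#' zero surviving template yields the no-amplification sentinel.
#'
#' @param allelic_dropout_rate per-allele dropout probability in \[0,1\].
#' @param assay_failure_rate per-well amplification failure probability.
#' @param ct_baseline Ct (cycles) of a two-copy template.
#' @param ct_per_copy_shift Ct shift per template halving (cycles); default 1.
#' @param ct_sd Gaussian Ct noise standard deviation (cycles).
#' @param no_amp_sentinel Ct value recorded for no amplification.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(allelic_dropout_rate = 0.1, assay_failure_rate = 0.05,
                         ct_baseline = 22, ct_per_copy_shift = 1,
                         ct_sd = 0.2, no_amp_sentinel = 40) {
  abort_if(allelic_dropout_rate < 0 || allelic_dropout_rate > 1,
           "allelic_dropout_rate must be in [0,1]")
  abort_if(assay_failure_rate < 0 || assay_failure_rate > 1,
           "assay_failure_rate must be in [0,1]")
  abort_if(ct_sd < 0, "ct_sd must be >= 0")
  structure(list(allelic_dropout_rate = allelic_dropout_rate,
                 assay_failure_rate = assay_failure_rate,
                 ct_baseline = ct_baseline,
                 ct_per_copy_shift = ct_per_copy_shift,
                 ct_sd = ct_sd,
                 no_amp_sentinel = no_amp_sentinel),
            class = "noise_config")
}

#' Zero-noise configuration (deterministic readout)
#' @return A `noise_config` with all stochastic terms set to zero.
#' @export
noise_free <- function() {
  noise_config(allelic_dropout_rate = 0, assay_failure_rate = 0, ct_sd = 0)
}

#' Simulate a clonal evolution ground truth
#'
#' Builds a rooted subclone tree whose root is the germline state (all
#' markers wild type, two copies everywhere). The first subclone under the
#' root carries all truncal markers (the founder lesions present in every
#' leukaemic cell, e.g. the patient-specific fusion plus a bi-allelic
#' CDKN2A loss). Remaining markers are distributed over the later edges so
#' that every subclone has a distinct genotype; along any root-to-node path
#' sequence states are non-decreasing and copy numbers non-increasing
#' (irreversibility).
#'
#' `reiterative_spec` plants independent parallel hits of the same gene:
#' for each `(gene, n)` entry, `n` distinct indel markers of that gene are
#' appended to the panel and placed on `n` divergent branches (siblings of
#' one another), so no two instances lie on the same root-to-leaf path.
#'
#' @param n_subclones number of observed subclones (>= 1).
#' @param markers a [marker_table()]; must contain all `truncal_markers`.
#' @param truncal_markers ids of markers placed on the root edge.
#' @param reiterative_spec optional list of `list(gene=, n=)` (or
#'   two-element vectors) requesting `n` independent hits of `gene`.
#' @param frequencies optional clone frequency vector (length
#'   `n_subclones`, non-negative, summing to 1); defaults to equal.
#' @param seed integer seed; the same seed reproduces the object exactly.
#' @return An object of class `clonal_truth` with fields `parent` (parent
#'   index per node, `NA` for the germline root), `node_ids`, `genotypes`
#'   (nodes x markers, raw states), `frequencies` (per subclone),
#'   `markers`, `seed`.
#' @export
make_truth <- function(n_subclones, markers, truncal_markers,
                       reiterative_spec = NULL, frequencies = NULL,
                       seed = 1L) {
  abort_if(!is_count(n_subclones), "n_subclones must be a positive integer")
  abort_if(!all(truncal_markers %in% markers$id),
           "truncal markers must be a subset of the marker panel")
  if (!is.null(reiterative_spec)) {
    for (spec in reiterative_spec) {
      gene <- as.character(spec[[1]]); n_hits <- as.integer(spec[[2]])
      abort_if(n_hits < 2, "a reiterative spec needs >= 2 independent hits")
      markers <- rbind(markers, marker_table(
        id = sprintf("%s_hit%d", gene, seq_len(n_hits)),
        class = "indel", gene = gene, steps = 1L))
    }
  }
  if (is.null(frequencies)) frequencies <- rep(1 / n_subclones, n_subclones)
  abort_if(length(frequencies) != n_subclones,
           "frequency vector length must equal n_subclones")
  abort_if(any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-8,
           "frequencies must be non-negative and sum to 1")

  n_nodes <- n_subclones + 1L              # node 1 = germline root
  m <- nrow(markers)
  reiter_ids <- unlist(lapply(reiterative_spec, function(spec)
    sprintf("%s_hit%d", as.character(spec[[1]]), seq_len(as.integer(spec[[2]])))))
  assignable <- setdiff(markers$id, c(truncal_markers, reiter_ids))

  truth <- with_seed(seed, {
    resample1 <- function(x) x[sample.int(length(x), 1L)]  # length-1 safe
    parent <- rep(NA_integer_, n_nodes)
    parent[2L] <- 1L                       # truncal clone under the root
    ## reiterative hits need pairwise-divergent branches: reserve sibling
    ## nodes directly under the truncal clone for them
    n_reiter_nodes <- if (is.null(reiter_ids)) 0L else
      sum(vapply(reiterative_spec, function(s) as.integer(s[[2]]), 1L))
    abort_if(n_reiter_nodes > n_subclones - 1L,
             "not enough subclones to host the requested reiterative hits")
    reiter_nodes <- if (n_reiter_nodes) 2L + seq_len(n_reiter_nodes) else integer(0)
    if (n_nodes >= 3L) for (v in 3:n_nodes) {
      parent[v] <- if (v %in% reiter_nodes) 2L else resample1(2:(v - 1L))
    }
    ## deal markers to non-truncal edges: one each first (distinct genotypes),
    ## then the surplus at random
    edge_nodes <- setdiff(seq_len(n_nodes)[-1L], 2L)   # nodes whose inbound edge gets markers
    assign_to <- integer(0)
    pool <- sample(assignable)
    free_nodes <- setdiff(edge_nodes, reiter_nodes)
    abort_if(length(pool) < length(free_nodes),
             "need at least one non-truncal marker per non-truncal subclone")
    edge_of <- setNames(rep(NA_integer_, length(pool)), pool)
    if (length(free_nodes)) edge_of[seq_along(free_nodes)] <- free_nodes
    ## surplus markers are dealt round-robin over a shuffled edge order so
    ## marker load per edge stays as even as possible (e.g. 2(k-1) markers
    ## over k-1 edges gives exactly 2 per edge)
    surplus <- which(is.na(edge_of))
    if (length(surplus) && length(edge_nodes)) {
      cyc <- sample(edge_nodes)
      edge_of[surplus] <- rep_len(cyc, length(surplus))
    }
    edge_of <- edge_of[!is.na(edge_of)]    # no non-truncal edges: markers stay wt
    ## reiterative markers: one per reserved sibling node
    if (n_reiter_nodes)
      edge_of <- c(edge_of, setNames(reiter_nodes, reiter_ids))

    G <- matrix(rep(germline_genotype(markers), each = n_nodes),
                nrow = n_nodes, dimnames = list(NULL, markers$id))
    apply_marker <- function(g, mid) {
      mk <- markers[markers$id == mid, ]
      if (mk$class == "cn_loss") g[mid] <- max(0L, g[mid] - mk$steps)
      else g[mid] <- min(2L, g[mid] + mk$steps)
      g
    }
    ## breadth-first fill so parents are complete before children
    for (v in order(seq_len(n_nodes))) {
      if (v == 1L) next
      g <- G[parent[v], ]
      mids <- if (v == 2L) truncal_markers else names(edge_of)[edge_of == v]
      for (mid in mids) g <- apply_marker(g, mid)
      G[v, ] <- g
    }
    list(parent = parent, genotypes = G)
  })

  out <- structure(list(
    parent = truth$parent,
    node_ids = c("N", paste0("C", seq_len(n_subclones))),
    genotypes = truth$genotypes,
    frequencies = setNames(as.numeric(frequencies),
                           paste0("C", seq_len(n_subclones))),
    markers = markers,
    seed = as.integer(seed)), class = "clonal_truth")
  rownames(out$genotypes) <- out$node_ids
  validate_clonal_truth(out)
  out
}

#' Validate a clonal truth object
#'
#' Checks the irreversibility invariants: germline root, monotone marker
#' states along every root-to-node path, valid frequencies.
#'
#' @param truth a `clonal_truth`.
#' @return `truth`, invisibly; errors on violation.
#' @export
validate_clonal_truth <- function(truth) {
  abort_if(!inherits(truth, "clonal_truth"), "not a clonal_truth object")
  g0 <- germline_genotype(truth$markers)
  abort_if(!identical(unname(truth$genotypes[1L, ]), unname(g0)),
           "root genotype is not germline")
  S <- geno_to_steps(truth$genotypes, truth$markers)
  for (v in seq_along(truth$parent)[-1L]) {
    d <- S[v, ] - S[truth$parent[v], ]
    abort_if(any(d < 0),
             "irreversibility violated on edge into node ", truth$node_ids[v])
  }
  abort_if(any(truth$frequencies < 0) ||
             abs(sum(truth$frequencies) - 1) > 1e-8,
           "clone frequencies must be non-negative and sum to 1")
  invisible(truth)
}

#' Sample single cells from a clonal truth
#'
#' Cells are drawn multinomially from the clone frequencies; each cell's
#' genotype is exactly its clone's genotype (measurement noise is added
#' later by [simulate_ct_readout()]).
#'
#' @param truth a `clonal_truth`.
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed.
#' @return list with `genotypes` (cells x markers, raw states, rownames
#'   cell ids), `clone` (true clone id per cell), `markers`.
#' @export
sample_cells <- function(truth, n_cells, seed = 1L) {
  validate_clonal_truth(truth)
  abort_if(!is_count(n_cells), "n_cells must be a positive integer")
  clone_ids <- names(truth$frequencies)
  idx <- with_seed(seed,
    sample.int(length(clone_ids), n_cells, replace = TRUE,
               prob = truth$frequencies))
  G <- truth$genotypes[idx + 1L, , drop = FALSE]   # +1: node 1 is germline
  rownames(G) <- sprintf("cell_%04d", seq_len(n_cells))
  list(genotypes = G, clone = clone_ids[idx], markers = truth$markers)
}

#' Re-sample cells through a xenograft bottleneck
#'
#' Models transplantation read-out: either an explicit set of engrafting
#' clones with new frequencies (e.g. weight 1 on one clone for a
#' single-clone sweep), or a selection coefficient that re-weights the
#' diagnostic frequencies by `exp(selection_strength * n_changes)` so
#' later, more mutated clones are favoured.
#'
#' @param truth a `clonal_truth`.
#' @param engrafting_clones named numeric vector of engraftment weights
#'   over clone ids (need not sum to 1); mutually exclusive with
#'   `selection_strength`.
#' @param selection_strength numeric; log-fitness per evolutionary change.
#' @param n_cells number of xenograft cells to draw.
#' @param seed integer seed.
#' @return As [sample_cells()].
#' @export
simulate_xenograft <- function(truth, engrafting_clones = NULL,
                               selection_strength = NULL, n_cells, seed = 1L) {
  validate_clonal_truth(truth)
  abort_if(is.null(engrafting_clones) && is.null(selection_strength),
           "supply engrafting_clones or selection_strength")
  clone_ids <- names(truth$frequencies)
  if (!is.null(engrafting_clones)) {
    abort_if(length(engrafting_clones) == 0L, "engrafting clone set is empty")
    abort_if(!all(names(engrafting_clones) %in% clone_ids),
             "engrafting clones absent from truth: ",
             paste(setdiff(names(engrafting_clones), clone_ids), collapse = ", "))
    abort_if(any(engrafting_clones < 0) || sum(engrafting_clones) <= 0,
             "engraftment weights must be non-negative with positive sum")
    w <- setNames(numeric(length(clone_ids)), clone_ids)
    w[names(engrafting_clones)] <- engrafting_clones
  } else {
    S <- geno_to_steps(truth$genotypes, truth$markers)
    changes <- rowSums(S)[-1L]
    w <- truth$frequencies * exp(selection_strength * changes)
  }
  xtruth <- truth
  xtruth$frequencies <- w / sum(w)
  out <- sample_cells(xtruth, n_cells, seed = seed)
  rownames(out$genotypes) <- sub("^cell_", "xcell_", rownames(out$genotypes))
  out
}

#' Build a qPCR assay panel for a marker panel
#'
#' One duplicated assay per marker (mutation-specific for sequence
#' markers, copy-number for cn markers referenced to a control assay),
#' optional wild-type-allele assays used to resolve homozygosity, and one
#' control assay.
#'
#' @param markers a [marker_table()].
#' @param wt_allele_for marker ids that get a paired wild-type-allele
#'   assay (allows hom vs het resolution during calling).
#' @param control_id id of the control assay.
#' @return data.frame with columns `assay_id`, `marker_id`, `class`
#'   (`mutation_specific`, `wt_allele`, `copy_number`, `control`),
#'   `control_assay`, `n_reps`.
#' @export
make_assay_panel <- function(markers, wt_allele_for = character(),
                             control_id = "CTRL") {
  abort_if(!all(wt_allele_for %in% markers$id),
           "wt_allele_for must name markers in the panel")
  cn <- is_cn_marker(markers)
  panel <- data.frame(
    assay_id = markers$id,
    marker_id = markers$id,
    class = ifelse(cn, "copy_number", "mutation_specific"),
    control_assay = ifelse(cn, control_id, NA_character_),
    n_reps = 2L, stringsAsFactors = FALSE)
  if (length(wt_allele_for)) {
    panel <- rbind(panel, data.frame(
      assay_id = paste0(wt_allele_for, "__wt"),
      marker_id = wt_allele_for, class = "wt_allele",
      control_assay = NA_character_, n_reps = 2L))
  }
  rbind(panel, data.frame(assay_id = control_id, marker_id = NA_character_,
                          class = "control", control_assay = NA_character_,
                          n_reps = 2L))
}

validate_panel <- function(panel, markers) {
  abort_if(!all(c("assay_id", "marker_id", "class") %in% names(panel)),
           "malformed assay panel")
  abort_if(sum(panel$class == "control") < 1L,
           "panel must contain at least one control assay")
  covered <- panel$marker_id[panel$class %in% c("mutation_specific", "copy_number")]
  missing <- setdiff(markers$id, covered)
  abort_if(length(missing) > 0L,
           "markers without an assay: ", paste(missing, collapse = ", "))
  invisible(panel)
}

#' Simulate a duplicated Ct readout for sampled cells
#'
#' Per cell, allelic dropout removes each allele independently; both
#' duplicate wells then see the same surviving template but fail to
#' amplify independently. Mutation-specific (and wild-type-allele) assays
#' amplify only if at least one targeted allele survives; copy-number and
#' control assays follow the delta-Ct model of [noise_config()].
#'
#' @param true_genotypes cells x markers matrix of raw states (as from
#'   [sample_cells()]).
#' @param markers the [marker_table()].
#' @param panel an assay panel covering every marker
#'   ([make_assay_panel()]).
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @return data.frame with `cell_id` then `<assay>__rep1`, `<assay>__rep2`
#'   columns of Ct values (sentinel = no amplification).
#' @export
simulate_ct_readout <- function(true_genotypes, markers, panel,
                                noise = noise_config(), seed = 1L) {
  validate_panel(panel, markers)
  abort_if(!inherits(noise, "noise_config"), "noise must be a noise_config")
  n <- nrow(true_genotypes)
  ado <- noise$allelic_dropout_rate
  fail <- noise$assay_failure_rate
  sent <- noise$no_amp_sentinel

  with_seed(seed, {
    ## surviving allele counts per cell x marker
    mut_alleles <- wt_alleles <- copies <- NULL
    cn <- is_cn_marker(markers)
    st <- true_genotypes
    surv <- function(k) stats::rbinom(length(k), k, 1 - ado)
    mut_alleles <- matrix(0L, n, nrow(markers))
    wt_alleles <- matrix(0L, n, nrow(markers))
    copies <- matrix(0L, n, nrow(markers))
    for (j in seq_len(nrow(markers))) {
      if (cn[j]) {
        copies[, j] <- surv(st[, j])
      } else {
        mut_alleles[, j] <- surv(st[, j])
        wt_alleles[, j] <- surv(2L - st[, j])
      }
    }
    colnames(mut_alleles) <- colnames(wt_alleles) <- colnames(copies) <- markers$id

    one_rep <- function(template) {
      ## template = surviving target copies; 0 -> sentinel
      ct <- noise$ct_baseline + noise$ct_per_copy_shift * (2 - template) +
        stats::rnorm(n, 0, noise$ct_sd)
      ct[template <= 0L] <- sent
      ct[stats::runif(n) < fail] <- sent
      ct
    }

    out <- data.frame(cell_id = rownames(true_genotypes),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(panel))) {
      a <- panel[i, ]
      template <- switch(a$class,
        mutation_specific = mut_alleles[, a$marker_id],
        wt_allele         = wt_alleles[, a$marker_id],
        copy_number       = copies[, a$marker_id],
        control           = rep(2L, n))
      for (r in seq_len(a$n_reps))
        out[[sprintf("%s__rep%d", a$assay_id, r)]] <- one_rep(template)
    }
    out
  })
}

RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"

#' Simulate breakpoint-flanking sequences
#'
#' Generates i.i.d. uniform ACGT sequences, optionally embedding either a
#' full consensus recombination signal sequence (heptamer CACAGTG +
#' 12 or 23 bp spacer + nonamer ACAAAAACC) or the cryptic CACA tetramer,
#' at a recorded 0-based half-open offset on a recorded strand.
#'
#' @param n number of sequences.
#' @param length sequence length (>= 39 for a 23-spacer RSS).
#' @param embed one of `"none"`, `"consensus_rss"`, `"cryptic_caca"`.
#' @param spacer spacer length for `consensus_rss` (12 or 23).
#' @param seed integer seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and
#'   `info`, a data.frame of planted motif coordinates (`seq_id`, `embed`,
#'   `start`, `end`, `strand`; 0-based half-open; `NA` when `embed =
#'   "none"`).
#' @export
make_breakpoint_sequences <- function(n, length,
                                      embed = c("none", "consensus_rss",
                                                "cryptic_caca"),
                                      spacer = 23L, seed = 1L) {
  embed <- match.arg(embed)
  abort_if(!is_count(n) || !is_count(length), "n and length must be positive")
  motif_len <- switch(embed, none = 0L, cryptic_caca = 4L,
                      consensus_rss = 7L + as.integer(spacer) + 9L)
  abort_if(embed == "consensus_rss" && !spacer %in% c(12L, 23L),
           "spacer must be 12 or 23")
  abort_if(length < motif_len,
           "sequence length too small for the requested embed")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- character(n)
    info <- data.frame(seq_id = sprintf("bp_%03d", seq_len(n)), embed = embed,
                       start = NA_integer_, end = NA_integer_,
                       strand = NA_character_, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      s <- sample(bases, length, replace = TRUE)
      if (embed != "none") {
        motif <- switch(embed,
          cryptic_caca = "CACA",
          consensus_rss = paste0(RSS_HEPTAMER,
                                 paste(sample(bases, spacer, replace = TRUE),
                                       collapse = ""),
                                 RSS_NONAMER))
        strand <- sample(c("+", "-"), 1L)
        planted <- if (strand == "+") motif else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
        off <- sample.int(length - motif_len + 1L, 1L) - 1L   # 0-based
        s[(off + 1L):(off + motif_len)] <- strsplit(planted, "")[[1]]
        info$start[i] <- off
        info$end[i] <- off + motif_len
        info$strand[i] <- strand
      }
      seqs[i] <- paste(s, collapse = "")
    }
    sset <- Biostrings::DNAStringSet(seqs)
    names(sset) <- info$seq_id
    list(sequences = sset, info = info)
  })
}
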