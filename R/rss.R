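## Weighted-matrix scoring of recombination signal sequences (RSS) and
## fixed-motif searches, used to assess RAG recombinase involvement at
## deletion breakpoints. An RSS is heptamer (consensus CACAGTG) + 12 or
## 23 bp spacer + nonamer (consensus ACAAAAACC); the spacer contributes
## through its length only, not its bases.

#' Default RSS weight matrix
#'
#' A log-odds-style position weight model. The first three heptamer
#' positions (CAC, essentially required for RAG cleavage) carry the
#' largest weights; the remaining heptamer and all nonamer positions carry
#' uniform smaller weights. Every column attains its maximum at the
#' consensus base (CACAGTG / ACAAAAACC). The spacer is penalised per base
#' of deviation from the canonical 12 or 23 bp lengths. Any user matrix
#' with consensus-maximal columns may be substituted; score-bearing
#' outputs record which matrix was used.
#'
#' @param spacer_penalty_per_base score penalty per base of spacer-length
#'   deviation (default 1.5).
#' @param spacer_tolerance maximum deviation from canonical spacer length
#'   (default 1; set 0 for strict 12/23 spacers).
#' @param threshold reference score threshold for calling RAG support
#'   (default 8.55).
#' @return An object of class `rss_matrix`: `heptamer` and `nonamer`
#'   (4 x width weight matrices, rows ACGT), spacer penalty settings,
#'   `threshold`, `name`.
#' @export
default_rss_matrix <- function(spacer_penalty_per_base = 1.5,
                               spacer_tolerance = 1L, threshold = 8.55) {
  bases <- c("A", "C", "G", "T")
  col_w <- function(cons, w_match, w_mis) {
    sapply(strsplit(cons, "")[[1]], function(b) {
      v <- rep(w_mis, 4L)
      names(v) <- bases
      v[b] <- w_match
      v
    })
  }
  hept <- cbind(col_w("CAC", 1.5, -1.5), col_w("AGTG", 0.75, -0.75))
  nona <- col_w("ACAAAAACC", 0.75, -0.75)
  colnames(hept) <- strsplit("CACAGTG", "")[[1]]
  colnames(nona) <- strsplit("ACAAAAACC", "")[[1]]
  structure(list(heptamer = unname(hept), nonamer = unname(nona),
                 heptamer_consensus = "CACAGTG",
                 nonamer_consensus = "ACAAAAACC",
                 spacer_penalty_per_base = spacer_penalty_per_base,
                 spacer_tolerance = as.integer(spacer_tolerance),
                 threshold = threshold,
                 name = "sclonetree-default-logodds"),
            class = "rss_matrix")
}

base_codes <- function(seq) {
  x <- strsplit(toupper(as.character(seq)), "")[[1]]
  code <- match(x, c("A", "C", "G", "T"))    # NA for N / other
  abort_if(!all(x[is.na(code)] %in% "N"),
           "sequence contains characters outside A/C/G/T/N")
  code
}

#' Score a window against one weight-matrix component
#'
#' Sum of per-position weights; `N` bases contribute the column minimum
#' (conservative).
#'
#' @param window character string, length 7 (heptamer) or 9 (nonamer).
#' @param matrix an `rss_matrix`.
#' @param component `"heptamer"` or `"nonamer"`.
#' @return numeric score.
#' @export
pwm_score <- function(window, matrix = default_rss_matrix(),
                      component = c("heptamer", "nonamer")) {
  component <- match.arg(component)
  W <- matrix[[component]]
  code <- base_codes(window)
  abort_if(length(code) != ncol(W),
           component, " window must have length ", ncol(W))
  sum(vapply(seq_along(code), function(j) {
    if (is.na(code[j])) min(W[, j]) else W[code[j], j]
  }, numeric(1)))
}

## vector of component scores at every start position of a coded sequence
component_scores <- function(code, W) {
  w <- ncol(W)
  n <- length(code) - w + 1L
  if (n <= 0L) return(numeric(0))
  out <- numeric(n)
  for (j in seq_len(w)) {
    cj <- code[j:(j + n - 1L)]
    wj <- ifelse(is.na(cj), min(W[, j]), W[cbind(cj, j)])
    out <- out + wj
  }
  out
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a sequence for the best-scoring RSS windows
#'
#' Exhaustively evaluates every heptamer placement combined with every
#' allowed spacer length of each spacer class; the total score is
#' heptamer + nonamer + spacer-length penalty. Coordinates are 0-based
#' half-open; for hits on the minus strand they give the footprint of the
#' reverse-complemented motif on the input sequence.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param matrix an `rss_matrix` ([default_rss_matrix()]).
#' @param spacer_classes canonical spacer lengths to scan (default
#'   `c(12, 23)`).
#' @param both_strands also scan the reverse complement (default `TRUE`).
#' @param seq_id sequence id recorded in the hits.
#' @return list with `best` (one-row data.frame: the global best hit) and
#'   `per_class_strand` (best hit per spacer class and strand). Columns:
#'   `seq_id`, `strand`, `spacer_class`, `spacer_length`,
#'   `heptamer_start`, `heptamer_end`, `nonamer_start`, `nonamer_end`,
#'   `heptamer_score`, `nonamer_score`, `spacer_penalty`, `total`.
#' @export
scan_rss <- function(seq, matrix = default_rss_matrix(),
                     spacer_classes = c(12L, 23L), both_strands = TRUE,
                     seq_id = "seq") {
  seq <- toupper(as.character(seq))
  len <- nchar(seq)
  min_spacer <- min(spacer_classes) - matrix$spacer_tolerance
  abort_if(len < 7L + min_spacer + 9L,
           "sequence too short to host an RSS")
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq else revcomp_chr(seq)
    code <- base_codes(s)
    hsc <- component_scores(code, matrix$heptamer)
    nsc <- component_scores(code, matrix$nonamer)
    for (cls in spacer_classes) {
      best <- NULL
      for (d in -matrix$spacer_tolerance:matrix$spacer_tolerance) {
        L <- cls + d
        if (L < 0L) next
        pen <- -matrix$spacer_penalty_per_base * abs(d)
        ## heptamer at h (1-based), nonamer at h + 7 + L
        n_h <- len - (7L + L + 9L) + 1L
        if (n_h <= 0L) next
        h <- seq_len(n_h)
        tot <- hsc[h] + nsc[h + 7L + L] + pen
        i <- which.max(tot)
        cand <- list(h = i, L = L, pen = pen, total = tot[i],
                     hs = hsc[i], ns = nsc[i + 7L + L])
        if (is.null(best) || cand$total > best$total) best <- cand
      }
      if (is.null(best)) next
      ## 0-based half-open, mapped back to input coordinates for "-"
      h0 <- best$h - 1L
      n0 <- h0 + 7L + best$L
      if (strand == "-") {
        hept <- c(len - (h0 + 7L), len - h0)
        nona <- c(len - (n0 + 9L), len - n0)
      } else {
        hept <- c(h0, h0 + 7L)
        nona <- c(n0, n0 + 9L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, strand = strand, spacer_class = cls,
        spacer_length = best$L,
        heptamer_start = hept[1L], heptamer_end = hept[2L],
        nonamer_start = nona[1L], nonamer_end = nona[2L],
        heptamer_score = best$hs, nonamer_score = best$ns,
        spacer_penalty = best$pen, total = best$total,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  per <- per[order(-per$total, per$strand, per$spacer_class), , drop = FALSE]
  rownames(per) <- NULL
  list(best = per[1L, , drop = FALSE], per_class_strand = per,
       matrix = matrix$name)
}

#' Find exact motif occurrences (both strands, overlaps allowed)
#'
#' Searches for exact matches of the given motifs (by default the RSS
#' consensus heptamer, nonamer, and the cryptic CACA tetramer associated
#' with RAG-mediated breakpoints), optionally restricted to a window
#' around a declared breakpoint coordinate.
#'
#' @param seq DNA sequence (character or [Biostrings::DNAString]).
#' @param motifs character vector of motifs over ACGT.
#' @param breakpoint optional 0-based inter-base breakpoint coordinate.
#' @param window half-width (bp) of the search window around
#'   `breakpoint` (default 50).
#' @param both_strands search the reverse complement too.
#' @return data.frame `motif`, `strand`, `start`, `end` (0-based
#'   half-open, input-sequence coordinates).
#' @export
find_fixed_motifs <- function(seq, motifs = c("CACAGTG", "ACAAAAACC", "CACA"),
                              breakpoint = NULL, window = 50L,
                              both_strands = TRUE) {
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  len <- length(s)
  rows <- list()
  for (motif in motifs) {
    for (strand in if (both_strands) c("+", "-") else "+") {
      pat <- if (strand == "+") motif else revcomp_chr(motif)
      m <- Biostrings::matchPattern(pat, s)
      if (length(m) == 0L) next
      st <- Biostrings::start(m) - 1L          # to 0-based
      en <- Biostrings::end(m)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, strand = strand, start = st, end = en,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), strand = character(0),
               start = integer(0), end = integer(0))
  if (!is.null(breakpoint) && nrow(out)) {
    out <- out[out$end > breakpoint - window &
                 out$start < breakpoint + window, , drop = FALSE]
  }
  out <- out[order(out$motif, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise best RSS scores over a set of breakpoints
#'
#' @param best_scores named numeric vector (or data.frame with columns
#'   `breakpoint_id`, `score`) of the best RSS score per breakpoint.
#' @param threshold reference threshold above which a score is taken as
#'   evidence of RAG involvement (default 8.55).
#' @return list with `max_score`, `n_above`, `above` (breakpoint ids),
#'   `classification` (`"no RAG support"` unless any score reaches the
#'   threshold), `per_breakpoint`.
#' @export
summarize_breakpoint_rss <- function(best_scores, threshold = 8.55) {
  if (is.data.frame(best_scores)) {
    df <- data.frame(breakpoint_id = best_scores$breakpoint_id,
                     score = best_scores$score, stringsAsFactors = FALSE)
  } else {
    abort_if(length(best_scores) == 0L, "need at least one breakpoint")
    df <- data.frame(breakpoint_id = names(best_scores) %||%
                       paste0("bp", seq_along(best_scores)),
                     score = as.numeric(best_scores),
                     stringsAsFactors = FALSE)
  }
  abort_if(nrow(df) == 0L, "need at least one breakpoint")
  above <- df$breakpoint_id[df$score >= threshold]
  list(max_score = max(df$score),
       n_above = length(above),
       above = above,
       classification = if (length(above)) "RAG support possible"
                        else "no RAG support",
       threshold = threshold,
       per_breakpoint = df)
}
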