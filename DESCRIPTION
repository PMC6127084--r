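Package: sclonetree
Title: Subclonal Architecture from Single-Cell Genotyping in Acute Leukaemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct subclonal architecture of acute
    lymphoblastic leukaemia from single-cell measurements. Converts
    duplicated single-cell multiplex qPCR Ct matrices into per-cell
    genotype calls with quality control, collapses cells into subclones,
    and infers maximum-parsimony clonal phylogenies under an ordered
    irreversible character model (sequence mutations 0->1->2, copy
    number 2->1->0) with exhaustive enumeration of co-optimal trees,
    inferred ancestral subclones, and cell-level bootstrap support.
    Includes a containment-ordering builder for multicolour-FISH signal
    patterns, a weighted-matrix recombination-signal-sequence (RSS)
    scanner for assessing RAG recombinase involvement at deletion
    breakpoints, cohort driver-frequency summaries, and a
    diagnosis-versus-xenograft compartment comparison. A seeded
    synthetic-data generator emulates the data structure of such studies
    (clonal ground truths, allelic dropout, assay failure, xenograft
    bottlenecks, breakpoint sequences) so every stage is testable
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
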