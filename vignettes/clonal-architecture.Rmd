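---
title: "Reconstructing subclonal architecture from single-cell genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing subclonal architecture from single-cell genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclonetree)
```

## The problem

*STIL-TAL1*+ T-cell acute lymphoblastic leukaemia carries a patient-specific
interstitial 1p33 deletion fusing *STIL* to *TAL1*, typically together with
loss of the *CDKN2A/CDKN2B* locus on 9p21.3, and a variable complement of
secondary lesions (*PTEN* indels and deletions, *NOTCH1* mutations, 6q
loss). A diagnostic sample is not a homogeneous clone but a set of related
subclones produced by branching evolution from a common ancestor. This
package reconstructs that architecture from single-cell measurements:
multiplex qPCR genotyping of a few hundred single cells over a small driver
panel, multicolour FISH signal counts, and paired xenograft read-outs. A
seeded synthetic-data generator reproduces the structure of such data so
that every stage of the pipeline can be tested against a known ground
truth.

## The character model

Each tracked lesion ("marker") is an ordered, irreversible character:

* sequence markers (fusion, SNV, indel): states 0 (wild type) → 1
  (heterozygous) → 2 (homozygous), never decreasing;
* copy-number markers: copies 2 → 1 → 0, never increasing.

Both families map onto a common "steps from germline" scale on which every
evolutionary change is a unit increment. Back-mutation of an indel or
re-gain of a deleted locus is biologically implausible on leukaemia time
scales, so reversals carry infinite cost (a Camin–Sokal-style asymmetric
model). Independent hits of the same gene on divergent branches (parallel,
"reiterative" evolution) are allowed and are in fact one of the signatures
the pipeline is designed to expose.

A clone tree is a rooted tree whose root is the germline state, whose nodes
are observed or inferred subclone genotypes, and whose edges are labelled
with the unit changes they carry; the branch length of an edge equals its
number of changes, so the sum of branch lengths is the parsimony score.

## Tree search

`infer_parsimony_trees()` must return *all* co-optimal trees — the data can
genuinely underdetermine the order of late events, and reporting a single
arbitrary optimum would overstate certainty (the package's standard
five-subclone example returns exactly two trees that differ in the parent
of the latest clone). The search therefore:

1. enumerates every rooted binary leaf topology over the observed
   subclones, treating the germline as a fixed extra taxon ((2k−3)!!
   topologies for k subclones; exhaustive enumeration is feasible because
   cases carry at most ~8 detected subclones);
2. scores each topology with per-character Sankoff dynamic programming
   under the asymmetric cost matrix (for binary topologies the optimal
   interior assignment is the componentwise minimum of the descendant
   states, which makes an independent closed-form oracle possible — see
   `brute_force_min_score()`);
3. contracts zero-change edges, which lets observed genotypes occupy
   internal positions and leaves inferred ancestors only where they reduce
   the score;
4. deduplicates by the multiset of (parent genotype, child genotype) edges
   and orders the survivors canonically, so output is deterministic.

The practical search bound (`max_subclones = 9`, 135,135 topologies) is a
deliberate design point: beyond that, heuristic search would be needed and
the completeness guarantee for the co-optimal set would be lost.

## Genotype calling and its thresholds

Single-cell qPCR assays are run in duplicate. The calling rules are
deliberately conservative and fully configurable:

* a well "amplifies" if its Ct is below `ct_max` (default 38 cycles, just
  under the 40-cycle no-amplification sentinel);
* mutation-specific assays: both duplicates amplify → positive, both dark →
  negative, discordant → missing. Treating discordance as missing rather
  than positive trades sensitivity for protection against amplification
  artifacts;
* copy number: the mean ΔCt against a control assay is banded by two
  cutpoints, default (0.5, 1.5) ΔCt. These match the ~1 cycle per template
  halving of ideal qPCR; both assay wells dark with amplifying controls is
  called 0 copies, and control failure gives NA;
* homozygosity of a sequence marker is only called when the panel carries a
  paired wild-type-allele assay that is negative; otherwise zygosity is
  capped at heterozygous. This abstracts the single-cell Sanger step that a
  wet-lab workflow would use to resolve zygosity.

QC operates on cells, not wells: a cell is removed when its controls failed
or when more than `max_missing_frac` of its marker calls are missing.

## Subclone detection under allelic dropout

Allelic dropout (ADO) — losing one allele of a single cell at lysis or
capture — is the dominant noise mode of single-cell genotyping and acts
*before* the duplicate wells, so duplicates cannot rescue it. Two
consequences drive the design of `collapse_subclones()`:

* A detection threshold (`min_cells`) is required: genotype classes below
  it are reported as "below the level of reliable detection" rather than
  silently dropped, mirroring how low-frequency or extinct subclones are
  displayed as inferred in published clonal diagrams.
* Dropout moves calls in a *known direction* (a heterozygous mutation reads
  wild type; a retained locus loses observed copies). A small class that
  differs from a much larger class by exactly one marker, shifted one step
  in the dropout direction, is therefore most plausibly that larger clone
  seen through dropout. The optional `absorb_dropout_classes` rule merges
  such satellite classes into their parent class before thresholding. The
  default size ratio of 3 follows from the generative model: with ADO
  around 0.1 and per-well failure around 0.05, a clone's complete-genotype
  class outweighs each of its single-dropout satellites by a factor of
  roughly `0.81 / 0.10` ≈ 3.5 per heterozygous marker. Absorption is safe
  whenever real subclones differ by at least two markers, because a single
  dropout can then never bridge two real clones; with single-marker edges
  it should stay off (its default).

Cells with missing calls are assigned to a detected subclone only when
exactly one subclone matches all their observed markers; otherwise they are
counted as unassigned. Counts always reconcile: assigned + unassigned +
below-threshold = input cells.

## Bootstrap support

`bootstrap_support()` resamples **cells** (rows) with replacement,
re-collapses and re-infers per replicate, and reports for each node of the
best full-data tree the percentage of replicates whose co-optimal trees
contain a node with the same genotype. Cells rather than characters are
resampled because the marker panel is small (5–10 markers; character
resampling would be degenerate) and the relevant sampling noise is in clone
frequencies. Ties among co-optimal full-data trees are broken by the
canonical ordering, which is stated in the output rather than hidden.

## FISH containment ordering

Multicolour FISH yields per-cell signal counts for a handful of probes. The
fusion probe is a sub-deletion design: a normal cell shows two co-localised
red–green pairs, and a fusion cell loses one red signal while keeping the
green control, encoded here as the number of intact pairs. Patterns
(identical signal tuples) are ordered by lesion containment under the same
irreversible model: pattern A is ancestral to B iff every lesion of A is at
most as severe as B's. Each pattern attaches to its unique maximal
strictly-contained pattern; incomparable maximal lower bounds attach the
pattern to their meet (added as an inferred node when unobserved) and flag
it ambiguous. Signal gains cannot be ordered by this model and raise an
error rather than being silently placed. An optional absorption flag (off
by default) folds patterns one hybridisation-failure away from a ≥10×
larger pattern into it; FISH dropout exists but no published correction
rule is available, so the default leaves the data untouched.

## RSS scoring

To ask whether deletion breakpoints look RAG-mediated, the package scans
breakpoint-flanking sequence for recombination signal sequences: heptamer
(consensus CACAGTG) + 12 or 23 bp spacer + nonamer (consensus ACAAAAACC).
The shipped weight matrix is a documented log-odds-style model of this
package: the first three heptamer positions (CAC), essentially required for
RAG cleavage, carry weights ±1.5; the remaining heptamer and all nonamer
positions carry ±0.75; every column is maximal at the consensus base. The
spacer contributes through its length only: 0 at the canonical 12/23 bp,
−1.5 per base of deviation, with ±1 bp tolerated by default (strict
spacers via `spacer_tolerance = 0`). `N` bases score the column minimum.
Any user matrix with consensus-maximal columns can be substituted, and all
score-bearing outputs record which matrix was used — scores are only
comparable within one matrix, so the conventional 8.55 reference threshold
is meaningful only for the matrix it was derived with. Coordinates are
0-based half-open throughout; minus-strand hits report the footprint of the
reverse-complemented motif on the input sequence.

## The synthetic-data generator

`make_truth()`/`sample_cells()`/`simulate_ct_readout()` emulate the
structure of a single-cell qPCR study: a truncal fusion plus bi-allelic
copy-number loss on the root edge, 3–8 subclones with subclonal SNVs,
indels and losses (optionally reiterative same-gene hits on divergent
branches), a few hundred cells per case, duplicate assays, per-allele ADO
shared across duplicates, independent per-well amplification failure, and a
ΔCt generative model (baseline 22, one cycle per copy halving, Gaussian
noise sd 0.2, sentinel 40). `simulate_xenograft()` re-samples clones
through an engraftment bottleneck, from a single-clone sweep to neutral
engraftment. `make_breakpoint_sequences()` plants consensus RSS or cryptic
CACA motifs at recorded offsets in uniform background sequence.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: doublets and ambient DNA, PCR efficiency
differences and Ct curve shapes, per-assay dropout heterogeneity,
cross-contamination, FISH hybridisation noise beyond signal counts, and any
non-uniform sequence composition around real breakpoints. The study the
generator mirrors does not report its assay failure or dropout rates, so
the defaults (ADO 0.1, failure 0.05) are free simulation parameters chosen
from the range typical of single-cell qPCR, not estimates of any
laboratory's rates.

## Numerical and degenerate-input choices

* All randomness flows through explicit `seed` arguments; no function
  leaves global RNG state behind.
* A single observed subclone yields the trivial root→clone tree; an
  observed germline genotype merges with the root node.
* Collapse and pattern ordering break ties deterministically (count, then
  genotype key), so equal inputs give byte-identical outputs.
* Copy numbers above 2 (gains) are rejected at validation everywhere — the
  irreversible loss model cannot represent them.
* Empty compartments, empty FISH tables, all-NA zygosity requests and
  too-short scan sequences raise informative errors instead of returning
  empty results.

## Problem sizes used by the shipped experiments

The package's own experiments run at the scale of the study design they
mirror: 20-sample cohort tables; five-subclone cases of ~300 cells for
topology recovery (50 simulations); 200 random instances of ≤7 subclones
and ≤10 markers for the oracle-equivalence check; 100 planted plus 100
random 150 bp sequences for the RSS separation and strand-symmetry
properties; 1,000 cells for the zero-noise round trip. On a single CPU the
full set completes in well under five minutes.

## Limitations

* The exhaustive search is limited to ~9 subclones; larger panels need
  heuristic tree search, which this package intentionally does not provide.
* Parsimony has no error model: systematically biased dropout can in
  principle produce a well-supported wrong topology. The
  SCITE/OncoNEM-style likelihood approaches address this at much higher
  computational cost.
* The RSS matrix is this package's own; absolute scores are not comparable
  with values computed under other laboratories' weight matrices.
* Multiple copy-number losses of the same locus with distinct breakpoints
  collapse to one copy-number state — qPCR copy-number assays cannot
  distinguish them, and no attempt is made to resolve them.
* Bootstrap support is a stability measure under cell resampling, not a
  posterior probability.

## A worked example

```{r example, eval = FALSE}
library(sclonetree)

markers <- marker_table(
  id    = c("STIL_TAL1", "CDKN2A", "NOTCH1", "FREM2", "PIK3CD"),
  class = c("fusion", "cn_loss", "snv", "snv", "snv"),
  steps = c(1, 2, 1, 1, 1))

genotypes <- rbind(
  C1 = c(1, 0, 0, 0, 0),   # fusion + biallelic CDKN2A loss (truncal)
  C2 = c(1, 0, 1, 0, 0),   # + NOTCH1
  C3 = c(1, 0, 1, 1, 0),   # + FREM2
  C4 = c(1, 0, 1, 0, 1),   # + PIK3CD
  C5 = c(1, 0, 1, 1, 1))   # latest clone: FREM2 and PIK3CD

sc <- subclone_set(genotypes, markers, counts = c(120, 80, 50, 40, 18))
trees <- infer_parsimony_trees(sc)
length(trees)            # 2 equally parsimonious trees
attr(trees, "score")     # 7 evolutionary changes
trees[[1]]
detect_reiterative_events(trees)
```
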