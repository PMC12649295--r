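---
title: "Predicting taxon-specific similarity cutoffs for DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting taxon-specific similarity cutoffs for DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcut)
```

## The problem

Sequence similarity is the workhorse of DNA-barcode identification of fungi
and yeasts: a query (an ASV from a metabarcoding run, a Sanger read from an
isolate) is compared against reference barcodes, and a name is accepted when
the similarity clears a threshold. A single fixed threshold, however, is
wrong almost everywhere: the ITS region evolves at very different rates
across lineages, the LSU D1/D2 domains are far more conserved than ITS1, and
some species pairs are outright identical in a given marker. `barcut`
implements the machinery for deriving *marker- and taxon-specific* cutoffs
from a reference dataset with a trusted taxonomy, and for using them in
rank-wise classification.

## Similarity scores

Pairwise similarity is the percent identity of the best local alignment,
with gap columns counted in the denominator, matching the "pident"
convention of tabular search output. Two safeguards:

* **Minimum alignment length.** Short alignments make unrelated sequences
  look similar. When the alignment length $l$ falls below a minimum $m$, the
  identity $s$ is down-weighted to $s \cdot l / m$; otherwise it is used
  unchanged. The conventional settings are $m = 400$ for full-length
  ITS/LSU barcodes and $m = 50$ for the short ITS1/ITS2 sub-regions, and
  these are the package defaults through `alignmentParams()`.
* **Ambiguity codes.** N and other IUPAC ambiguity codes always score as
  mismatches — a conservative choice that cannot inflate similarity.

The aligner is an exact affine-gap Smith–Waterman (match $+2$, mismatch
$-3$, gap open 5, gap extend 2 — the common nucleotide-search scheme, all
configurable). It is implemented in C++ for throughput, since building a
matrix means $\binom{n}{2}$ alignments, and the test suite verifies it
against `Biostrings::pairwiseAlignment`, an independent dynamic-programming
implementation, for both optimal scores and identity/length.

Matrices are sparse: scores below a retention floor (default 0.5) are
dropped, self-similarity is defined as 1 and never stored, and symmetry is
structural. All cutoff sweeps operate at 0.7 and above, so the floor bounds
memory without touching results; it is recorded in the object and in the
serialized TSV because the variation statistics use it as the value of
absent pairs (see below). Precomputed searches can be imported from the
standard 12-column tabular format; asymmetric hit lists are symmetrized by
taking the maximum of the two directions (the choice is documented rather
than prescribed by convention; mean or first-seen would also be defensible),
and only the highest-bit-score row per pair is used.

## Clustering and the F-measure

Clustering at threshold $t$ means taking connected components of the graph
with an edge wherever the stored score is at least $t$ (single linkage).
This is the simplest model consistent with species "merging into a group"
at a given similarity. Threshold comparisons use a $10^{-9}$ tolerance so
that grid values produced by `seq()` and scores produced by integer ratios
agree despite binary floating-point representation.

A clustering is scored against a taxonomic ground truth — the partition of
sequences by their name at one rank — with the clustering F-measure. For
class $k$ (size $n_k$) and cluster $j$ (size $n_j$) sharing $n_{kj}$
sequences, precision is $n_{kj}/n_j$, recall is $n_{kj}/n_k$, and
$F(k,j) = 2 n_{kj}/(n_k + n_j)$ is their harmonic mean. Each class
contributes its best $F$ over clusters, weighted by class size:

$$F = \sum_k \frac{n_k}{n}\,\max_j F(k,j).$$

$F = 1$ exactly when clusters coincide with classes. Sequences unannotated
at the evaluation rank cannot contribute ground truth, so both the
clustering and the evaluation are restricted to annotated ids. "Unannotated"
covers empty cells, `unidentified`, and species epithets that are only
`sp.` — the exact token list is a documented normalization choice.

## Cutoff prediction

`sweepPredict()` clusters at every threshold on a grid and returns the
smallest grid threshold attaining the maximal F (the *cutoff*) together
with that F (the *resolving power*). Defaults: grid 0.70–1.00 in steps of
0.001, matching the three-decimal precision at which such cutoffs are
conventionally reported; for genus- and higher-level delineation a lower
start (e.g. 0.5) is advisable because optimal thresholds fall well below
0.7 in divergent groups. The smallest-threshold tie rule matters on
plateaus: it is the inclusive choice and stays stable when divergent
outliers are added. The sweep is evaluated incrementally (edges added in
descending score order while the grid is walked downward), so a full sweep
costs little more than a single clustering.

*Global* cutoffs use the whole dataset as scope; *local* cutoffs restrict
the sweep to one taxonomic group (e.g. predict species-level cutoffs inside
each genus). Local prediction applies a group-eligibility filter, since tiny
or degenerate groups yield meaningless optima: a group enters only with
more than 30 sequences (exclusive bound), at least 5 ground-truth groups,
and no single group holding more than 70% of the sequences. All three
bounds are parameters of `eligibilityFilter()`. Counting uses the ids
annotated at the level rank — the only ones that can contribute ground
truth.

When a taxon's own prediction is absent or weakly supported,
`bestCutoff()` walks its ancestor chain (genus → family → order → class →
phylum → global) and returns the entry with the highest confidence,
breaking ties toward the most specific entry and recording the fallback
source.

## Indistinguishable species

Species whose sequences co-cluster at 100% similarity cannot be separated
by the marker at all. `indistinguishableComplexes()` clusters at score 1.0
(exactly, after adjustment; the tolerance is configurable through the
threshold argument) and reports every cross-species co-membership as a
complex, taking the transitive closure when a species spans clusters.
Same-species co-clustering never creates a complex. `deduplicateSpecies()`
retains one representative per complex — the alphabetically first member
unless overridden, a determinism choice — so cutoffs can be re-predicted on
the separable remainder. Keeping indistinguishable pairs in the dataset
pushes predicted cutoffs up (the sweep tries in vain to split identical
sequences) and caps the resolving power below 1; removing them lowers, or
at worst preserves, the cutoff and raises the confidence, and the test
suite asserts exactly this direction on planted fixtures.

## Variation statistics and distributions

`groupVariation()` reports the minimum and median pairwise similarity over
all within-group pairs, per group; `rankSummary()` takes medians across
groups per rank. Pairs absent from the sparse matrix are valued at the
floor, not zero — the floor is the only information retained about them,
and the convention makes the summaries reproducible given the same floor.
The median is over pair values, not per-sequence aggregates.
`taxonDistribution()` tabulates sequence and subgroup counts per taxon and
the share of the top-5 taxa per rank, a tabular stand-in for composition
charts.

## Classification

`classifySequences()` finds each query's best reference hit (single best
hit; top-k consensus is out of scope) and walks ranks species → phylum. At
each rank the applicable cutoff is the `bestCutoff()` chain started from
the hit's taxon at the rank above — species cutoffs are keyed by the hit's
genus, genus cutoffs by its family, and so on — falling back to the global
entry. The deepest rank whose cutoff the score reaches is accepted; names
below it are blanked. Queries shorter than $m$ are handled by the
length adjustment, not rejected. When two reference sets are used,
`mergeResults()` keeps, per query, the deeper assignment, then the higher
score, then the source whose label sorts first: depth-first merging
preserves the deeper assignments of a specialized reference set over a
stricter combined one.

## The synthetic generator

`simulateDataset()` generates datasets with the statistical structure the
analysis assumes, and with full ground truth:

* **Hierarchy and imbalance.** One random ancestral sequence per phylum;
  recursive descent through class, order, family, genus, species, strain.
  Children counts are fixed integers or ranges sampled with a geometric
  tail, which produces the few-dominant-genera imbalance typical of
  barcode reference collections.
* **Divergence ladder.** Each split introduces an expected substitution
  fraction that grows with rank height (defaults: species 0.005, genus
  0.05, family 0.12, order 0.18, class 0.25; strain noise 0.002). The
  species and genus defaults place within-species identities near 0.99 and
  congeneric identities near 0.95 — the regime where real ITS/LSU cutoffs
  live. Substitutions have a 2:1 transition:transversion ratio and 10% of
  edits are single-base indels; the analysis depends only on identity
  levels, so a more elaborate substitution model would add nothing
  testable. Edit counts are the stochastically rounded expectation
  (floor plus Bernoulli remainder) rather than binomial draws: every split
  is then guaranteed at least its expected divergence, which keeps the
  planted identity gap well-posed whenever ladder spacing dominates strain
  noise. Under a binomial model a fraction of species splits would draw
  zero substitutions and silently merge species.
* **Planted structure.** Indistinguishable complexes are planted by copying
  one species' sequences verbatim onto a congeneric species; a fraction of
  records can have their family annotation blanked to exercise rank-wise
  exclusion. Everything derives from one master seed, so fixtures are
  byte-reproducible.

`simulateQueries()` draws error-bearing reads: contiguous subsequences of
a random strain of the requested species, with substitutions at a given
error rate (no indels — a read-quality model, not an evolutionary one).

What passing tests on this generator do **not** show: real ITS has
intragenomic copy heterogeneity, length variation far beyond single-base
indels, chimeras and primer artifacts, and taxonomies with genuine
misannotations. The generator's clean hierarchy makes recovery tests
well-posed; it does not certify performance on noisy public data.

## Problem sizes and numerical choices

The shipped tests run at desk scale: cutoff-recovery sweeps use 20
generated datasets of 200 sequences (150–300 nt, $m = 50$), classification
uses ~200 queries against 64-sequence references, and the whole suite
completes in a few minutes on one CPU. The acceptance script
(`scripts/acceptance.R`) re-runs the same pipeline at the same sizes from a
command-line seed.

Degenerate inputs are rejected loudly: a ground truth with a single group
("degenerate truth"), empty id sets, duplicate ids, thresholds below the
matrix floor (warning — components may be under-merged). The sweep grid is
generated as `start + step * 0:k` and rounded to 9 decimals; all
threshold comparisons use the $10^{-9}$ tolerance noted above.

## Known limitations

* Single-linkage is the only clustering model; centroid/greedy variants
  would give different counts near the threshold.
* Cutoff confidence is a point estimate; no interval or cross-validation
  is attempted.
* The best-hit rule consults one reference; ties beyond the lexicographic
  rule are invisible.
* The generator's imbalance knob is coarse (geometric tails), and its
  divergence model is site-independent.
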