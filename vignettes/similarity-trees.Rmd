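---
title: "From BLAST report to curated homolog set: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From BLAST report to curated homolog set: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastree)
```

Assembling a good set of homologous sequences is the step that most often
decides whether a downstream phylogenetic analysis is interpretable.  A raw
BLAST report is a poor basis for that decision: hits are ranked by a scoring
scheme that favours long ungapped alignments, divergence is only shown
between the query and each hit (never between hits), and the metadata a
phylogeneticist actually filters on — taxonomy, coverage, mutual similarity
— is scattered or absent.  `blastree` post-processes a single-query BLAST
XML report into the objects that make triage easy: a query-anchored pseudo
multiple alignment, a neighbor-joining p-distance *similarity tree*, and a
set of composable hit-selection operations with FASTA/Newick export.

This vignette documents the model and procedure, the parameters that
matter, the numerical conventions, and what the synthetic-data generator
does and does not emulate.

## The pseudo multiple alignment (HSP stacking)

BLAST reports local gapped alignments (high-scoring pairs, HSPs) between
the query and each subject.  Because every HSP is expressed in query
coordinates, the hits can be *stacked*: each hit residue is placed in the
column of its homologous query residue.  The resulting matrix is exactly as
wide as the query, the query is its first (gap-free) row, and no joint
alignment is ever computed — which is what makes the construction fast
enough for thousands of hits.

Three rules complete the construction:

* **Concatenation.** Multiple HSPs of one hit that do not overlap on the
  query are written into the same row.  Overlap is a non-empty intersection
  of the query intervals; *adjacent* intervals do not overlap.
* **Duplicated domains.** When a hit contains repeats, each repeat unit
  produces an HSP over the same query region.  Only the highest-scoring
  pair is stacked; selection is greedy by descending bit score (ties: lower
  query start, then report order) and a lower-scoring HSP that overlaps an
  already-kept one is discarded *entirely*.  We deliberately do not trim
  partial overlaps: trimming would fabricate alignment columns that BLAST
  never reported.
* **Insertions are lossy.** A hit residue that aligns to a gap in the query
  has no column and is dropped.  Regions of a hit outside its kept HSPs
  are gap characters.

The price of stacking is accuracy: a pseudo alignment is not a real MSA,
and columns spanning distinct HSPs of different hits were never aligned to
each other by any algorithm.  The package treats the matrix strictly as a
triage instrument.

## Distances and the similarity tree

Pairwise divergence is the uncorrected p-distance — the proportion of
differing sites among compared sites — in one of two site modes:

* `all_sites` (the default, and the mode used for the initial tree):
  pairwise deletion; each pair is compared over the columns where both rows
  have residues.  A pair with no comparable columns gets distance 1 and a
  warning rather than an error, so one fragmentary hit cannot abort a
  build.
* `gap_free`: only columns with a residue in *every* selected row are used.
  If no such column exists the build stops with an error that suggests
  `all_sites`, since silently returning an empty-site distance would be
  meaningless.

The tree is built by neighbor joining, implemented from the textbook
recurrences rather than delegated to an external alignment program, so that
its behaviour is fully specified and testable: the joined pair minimizes
`Q(i,j) = (m-2) d(i,j) - r_i - r_j`; ties are broken deterministically by
the smallest index pair in the current cluster order (new clusters are
appended last); negative branch lengths — a known NJ artefact on
non-additive input — are clamped to zero with the total deficit recorded on
the result.  On additive input the algorithm is exact, which the test suite
verifies against an independently coded NJ, against `ape::nj`, and (for
small trees) against exhaustive topology search with least-squares edge
fitting.  The tree is unrooted; with two leaves the single distance is
split in half.

The similarity tree is *not* a phylogeny: p-distances are uncorrected, the
alignment is approximate, and no support values are computed.  It is robust
enough to show approximate relationships — which is exactly what hit triage
needs — and users are expected to rebuild a proper phylogeny from the
exported FASTA afterwards.

## Selection model

All selection tools are pure functions from a result to a set of hit
labels, and they compose as set intersection, so the order in which filters
are applied never matters:

* **E-value threshold**, inclusive (`e_value <= t`).
* **Metric intervals**, closed on both ends, over bit score, pooled percent
  similarity, or query coverage.  A score-threshold "click" on the ranked
  score histogram is the interval `[t, Inf)`.
* **Taxonomy**: a hit matches a taxon when the taxon appears in its
  lineage; exclusion complements within the *annotated* hits only, so hits
  with unknown taxonomy never silently pass a taxonomic filter in either
  direction.
* **Top-N view**: the default tree shows the query plus the 100
  best-scoring hits among those passing the active filters; the remaining
  hits stay in the result for the bulk tools.  Reports are capped at 5,000
  hits at parse time.

Per-hit metrics are defined over the *kept* (post-resolution) HSPs, so they
are consistent with the stacked alignment: coverage is the length of the
union of kept HSP query intervals divided by the query length, and percent
similarity pools positives over columns (`100 * sum(positives) /
sum(align_len)`, a length-weighted pool, not a per-HSP average; identities
substitute for positives in nucleotide searches).

Hit-level score and E-value are those of the hit's best-bit-score HSP — the
report format does not define a hit-level value, and the best HSP is what
every BLAST front end displays.

## External sequences

Up to five user-supplied sequences can be added to a selection.  Each is
globally aligned to the ungapped query (Needleman–Wunsch, affine gaps) and
projected into query columns exactly as HSP stacking does, insertions
dropped.  Defaults: BLOSUM62 for protein, +2/−3 with gap open 5 and extend
2 for nucleotide; both matrix and gap costs are arguments, since no single
scheme suits every use.  The tree is then rebuilt on the enlarged
selection.

## Taxonomy

Lineages come from a local table in the NCBI taxdump layout (`nodes.dmp` /
`names.dmp`, pipe-delimited; only `scientific name` entries are indexed so
the name index stays unambiguous).  Loading verifies integrity: exactly one
root, no orphan parents, no cycles.  A hit's species is resolved from its
report taxid when present, otherwise from the last bracketed `[...]` span
of its description — the NR deflines convention — matched against the name
index; anything unresolvable degrades to `"unknown"` rather than failing.
A ~90-taxon subset of the real taxonomy ships with the package so every
example and test runs offline.  Tree leaves are renamed to species (with
accession suffixes on collision) and colored by their lineage name at a
configurable rank; the default rank is phylum, a level that separates
groups visibly without fragmenting typical result sets into dozens of
colors.

## BLASTX, TBLASTN and strand handling

Translated searches are post-processed at the protein level.  For BLASTX
the column space is the translated query in the reading frame of the
top-scoring HSP; within each hit only HSPs in the frame of that hit's best
HSP are considered, and hits whose best frame differs from the global one
cannot be projected onto the shared column space and are dropped with a
warning.  Cross-frame concatenation within one hit is rejected because a
single row cannot represent two reading frames.  Minus-strand nucleotide
HSPs are normalized at parse time (subject coordinates swapped, strand
recorded, alignment strings kept query-forward).  TBLASTX reports are
rejected outright: overlapping reading-frame alignments have no sequence-
level representation to stack.

## The synthetic-report generator

`simulate_dataset()` produces ground-truth datasets and emits them in the
BLAST XML dialect, so every module is testable without a network or a
BLAST installation.  Its model is deliberately minimal:

* Substitutions are i.i.d. uniform replacements — a mutated site takes one
  of the 19 other residues with equal probability — so on a star tree the
  expected query–hit p-distance equals `sub_rate` exactly, giving the test
  suite a closed-form expectation.
* On a `"random"` tree shape, a random bifurcating topology is drawn with
  the query at one leaf, and each edge substitutes sites with probability
  `sub_rate` scaled by a uniform(0.5, 1.5) edge factor.
* Indels (geometric lengths, mean 2) are applied on each hit's terminal
  branch only, which keeps the truth alignment to query coordinates exact.
* Engineered events exercise the stacking rules: a fraction of hits get a
  tandem duplication (two HSPs over the same query span with distinct,
  ordered scores) and a fraction get a long internal deletion that splits
  their alignment into two non-overlapping HSPs.
* Scores are synthetic (`2*identities - mismatches - 2*gaps`, floored at
  1) and E-values a fixed monotone transform (`10^(-bits/10)`): only their
  *ordering* matters to the tools under test, and no attempt is made to
  reproduce Karlin–Altschul statistics.

Defaults were fixed once from the statistical behaviour of the model: a
300-residue query (an ordinary protein length) makes p-distance noise small
enough (standard error about 0.013 at 5% divergence) that neighbor joining
recovers 12-leaf topologies reliably at `sub_rate = 0.05`, which is the
regime the end-to-end recovery checks use.  What the generator does *not*
emulate — compositional bias, rate heterogeneity across sites, realistic
E-value statistics, database search artefacts — bounds what passing tests
show: they validate the post-processing machinery, not BLAST itself.

## Problem sizes and determinism

The shipped checks run the generator at the scales the operating constants
refer to: a 6,000-hit report for the 5,000 cap, a 250-hit report for the
top-100 default view, 200 random additive matrices (5–12 leaves) for NJ
exactness, 500 small reports for the stacking laws and 100 for the filter
oracles.  Everything downstream of a seed is deterministic: the same seed
reproduces a dataset byte for byte, and `run_pipeline()` writes
byte-identical Newick for the same configuration.

## Known limitations

* Full subject sequences are not in the XML; FASTA export is flagged
  `partial` unless a subject database FASTA is supplied.
* The pseudo alignment discards hit insertions; positions present in a hit
  but absent from the query can never appear in any output alignment.
* `all_sites` distances use pairwise deletion; different pairs are
  therefore computed over different column sets, which can make the matrix
  slightly non-additive even for perfectly homologous rows.
* Merged or deleted taxids (`merged.dmp`) are not handled; the taxonomy
  table is whatever dump the user loads.
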