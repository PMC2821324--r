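# blastree

Phylogeny-oriented triage of BLAST results.

A BLAST search is usually the first step in building a dataset of
homologous sequences for phylogenetic analysis, but the raw report is a
poor instrument for the selection step: hits are ranked by alignment score
(which penalizes gapped, split alignments), divergence is only shown
between the query and each hit, and taxonomy is buried in description
lines.  `blastree` post-processes a single-query NCBI BLAST XML report
(BLASTN/BLASTP/BLASTX/TBLASTN, `-outfmt 5`) into the objects that make hit
triage easy, entirely offline:

* a **query-anchored pseudo multiple alignment** built by HSP stacking —
  each hit residue is placed in the column of its homologous query residue,
  non-overlapping HSPs of a hit are concatenated, and for duplicated
  domains only the highest-scoring repeat unit is kept;
* a **similarity tree**: neighbor joining on uncorrected p-distances
  (`d = mismatches / compared sites`, with pairwise-deletion or
  gap-free-site handling), with leaves renamed by species and colored by a
  chosen taxonomic rank.  NJ joins the pair minimizing
  `Q(i,j) = (m-2) d(i,j) - r_i - r_j` and is exact on additive distances;
* **selection tools** that compose as set intersections: inclusive E-value
  thresholds, closed intervals over bit score / pooled percent similarity /
  query coverage, taxon include/exclude via NCBI-taxdump lineages, and the
  top-100 default view (reports are capped at 5,000 hits);
* **export**: selected hits as FASTA (full sequences when a subject
  database FASTA is available, otherwise HSP-derived sequences flagged
  `partial`), trees as Newick, annotations and feature tables as TSV;
* a **seedable simulator** that evolves hits from a query along a known
  tree, engineers duplicated domains and split HSPs, and emits valid BLAST
  XML — so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(blastree)

## a synthetic 40-hit report with known ground truth (or any real
## single-query BLAST XML file)
truth <- simulate_dataset(n_hits = 40, query_len = 200, sub_rate = 0.08,
                          dup_fraction = 0.1, seed = 7)
emit_blast_xml(truth, "report.xml")

res <- parse_blast_xml("report.xml")
res <- annotate_hits(res, load_fixture_taxonomy())
res
#> <blast_result> blastp: query 'QUERY synthetic query protein' (200 residues) vs synthetic_db
#>   40 hits; best bit score 150.5 (HIT_0001)

head(hit_feature_table(res), 4)
#>     hit_id                species      e_value bit_score percent_similarity coverage
#> 1 HIT_0001       Escherichia coli 8.912509e-16     150.5               91.0        1
#> 2 HIT_0004 Pseudomonas aeruginosa 3.981072e-11     104.0               84.5        1
#> 3 HIT_0012            Danio rerio 2.238721e-10      96.5               82.5        1
#> 4 HIT_0003        Yersinia pestis 8.912509e-10      90.5               82.0        1
```

Each row is one hit: its best E-value and bit score, percent similarity
pooled over its kept HSPs, and the fraction of the query covered by them.

```r
msa  <- stack_hsps(res)                    # pseudo-MSA, width = query length
gap_free_site_count(msa, top_n_hits(res, 10))
#> [1] 200

tree <- rebuild_tree(res, top_n = 10)      # p-distance NJ tree
tree
#> <similarity_tree> 11 leaves, site mode all_sites, 6 taxonomy group(s)
write_newick(tree, "tree.nwk")
plot(tree)                                 # tips colored by phylum

## bulk selection: bacterial hits with E <= 1e-10
sel <- apply_selection(res,
  selection_state(e_value = 1e-10,
                  taxa = list(list(taxon = "Bacteria", include = TRUE))),
  load_fixture_taxonomy())
length(sel)
#> [1] 2
export_fasta(res, sel, "selected.fasta")

taxonomy_summary(res, load_fixture_taxonomy(), max_depth = 1)
#> root (no rank): 40
#>   Bacteria (superkingdom): 22
#>   Eukaryota (superkingdom): 16
#>   Archaea (superkingdom): 2
```

The tree has 11 leaves (the query plus the 10 best hits); the gap-free
counter reports how many alignment columns have a residue in every
selected row — the usable signal for the eventual phylogeny.  With a real
report, pass your own taxonomy dump to `load_taxdump()` and your query
FASTA to `parse_blast_xml()`.

A command-line front end with `parse`, `stack`, `tree`, `select`,
`export`, `simulate` and `run` subcommands is installed under `exec/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","blastree",package="blastree"))')" \
  tree --xml report.xml --query query.fasta --taxdump taxdump/ --out tree.nwk
```

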