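Package: blastree
Title: Phylogeny-Oriented Triage of BLAST Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processes NCBI BLAST XML reports for homolog dataset
    curation prior to phylogenetic analysis. Reconstructs a query-anchored
    pseudo multiple alignment by stacking high-scoring pairs (HSPs) onto
    query coordinates, computes p-distances and a neighbor-joining
    similarity tree with taxonomy-annotated leaves, and supports hit
    selection by E-value, score, percent similarity, alignment coverage
    and taxonomic rank, with FASTA and Newick export. Ships a seedable
    synthetic-report generator so the whole pipeline is testable without
    network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    ape,
    Biostrings,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
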