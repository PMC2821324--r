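# A small synthetic subset of the NCBI taxonomy (real taxids and names,
# hand-picked) used for tests, examples and the synthetic-report generator.
# Spans three superkingdoms and ten phyla down to 17 species.

fixture_taxa <- function() {
  d <- function(taxid, parent, rank, name)
    data.frame(taxid = taxid, parent = parent, rank = rank, name = name,
               stringsAsFactors = FALSE)
  rbind(
    d(1L, 1L, "no rank", "root"),
    ## Bacteria
    d(2L, 1L, "superkingdom", "Bacteria"),
    d(1224L, 2L, "phylum", "Proteobacteria"),
    d(1236L, 1224L, "class", "Gammaproteobacteria"),
    d(91347L, 1236L, "order", "Enterobacterales"),
    d(543L, 91347L, "family", "Enterobacteriaceae"),
    d(561L, 543L, "genus", "Escherichia"),
    d(562L, 561L, "species", "Escherichia coli"),
    d(590L, 543L, "genus", "Salmonella"),
    d(28901L, 590L, "species", "Salmonella enterica"),
    d(1903411L, 91347L, "family", "Yersiniaceae"),
    d(629L, 1903411L, "genus", "Yersinia"),
    d(632L, 629L, "species", "Yersinia pestis"),
    d(72274L, 1236L, "order", "Pseudomonadales"),
    d(135621L, 72274L, "family", "Pseudomonadaceae"),
    d(286L, 135621L, "genus", "Pseudomonas"),
    d(287L, 286L, "species", "Pseudomonas aeruginosa"),
    d(28211L, 1224L, "class", "Alphaproteobacteria"),
    d(356L, 28211L, "order", "Rhizobiales"),
    d(82115L, 356L, "family", "Rhizobiaceae"),
    d(357L, 82115L, "genus", "Agrobacterium"),
    d(358L, 357L, "species", "Agrobacterium tumefaciens"),
    d(1239L, 2L, "phylum", "Firmicutes"),
    d(91061L, 1239L, "class", "Bacilli"),
    d(1385L, 91061L, "order", "Bacillales"),
    d(186817L, 1385L, "family", "Bacillaceae"),
    d(1386L, 186817L, "genus", "Bacillus"),
    d(1423L, 1386L, "species", "Bacillus subtilis"),
    d(186826L, 91061L, "order", "Lactobacillales"),
    d(1300L, 186826L, "family", "Streptococcaceae"),
    d(1301L, 1300L, "genus", "Streptococcus"),
    d(1313L, 1301L, "species", "Streptococcus pneumoniae"),
    d(1117L, 2L, "phylum", "Cyanobacteria"),
    d(1118L, 1117L, "order", "Chroococcales"),
    d(1142L, 1118L, "genus", "Synechocystis"),
    d(1148L, 1142L, "species", "Synechocystis sp. PCC 6803"),
    ## Archaea
    d(2157L, 1L, "superkingdom", "Archaea"),
    d(28890L, 2157L, "phylum", "Euryarchaeota"),
    d(183939L, 28890L, "class", "Methanococci"),
    d(2182L, 183939L, "order", "Methanococcales"),
    d(2183L, 2182L, "family", "Methanococcaceae"),
    d(196118L, 2183L, "genus", "Methanocaldococcus"),
    d(2190L, 196118L, "species", "Methanocaldococcus jannaschii"),
    ## Eukaryota
    d(2759L, 1L, "superkingdom", "Eukaryota"),
    d(7711L, 2759L, "phylum", "Chordata"),
    d(40674L, 7711L, "class", "Mammalia"),
    d(9443L, 40674L, "order", "Primates"),
    d(9604L, 9443L, "family", "Hominidae"),
    d(9605L, 9604L, "genus", "Homo"),
    d(9606L, 9605L, "species", "Homo sapiens"),
    d(9989L, 40674L, "order", "Rodentia"),
    d(10066L, 9989L, "family", "Muridae"),
    d(10088L, 10066L, "genus", "Mus"),
    d(10090L, 10088L, "species", "Mus musculus"),
    d(186623L, 7711L, "class", "Actinopteri"),
    d(7952L, 186623L, "order", "Cypriniformes"),
    d(7954L, 7952L, "genus", "Danio"),
    d(7955L, 7954L, "species", "Danio rerio"),
    d(6656L, 2759L, "phylum", "Arthropoda"),
    d(50557L, 6656L, "class", "Insecta"),
    d(7147L, 50557L, "order", "Diptera"),
    d(7214L, 7147L, "family", "Drosophilidae"),
    d(7215L, 7214L, "genus", "Drosophila"),
    d(7227L, 7215L, "species", "Drosophila melanogaster"),
    d(6231L, 2759L, "phylum", "Nematoda"),
    d(119089L, 6231L, "class", "Chromadorea"),
    d(6236L, 119089L, "order", "Rhabditida"),
    d(6243L, 6236L, "family", "Rhabditidae"),
    d(6237L, 6243L, "genus", "Caenorhabditis"),
    d(6239L, 6237L, "species", "Caenorhabditis elegans"),
    d(35493L, 2759L, "phylum", "Streptophyta"),
    d(3398L, 35493L, "class", "Magnoliopsida"),
    d(3699L, 3398L, "order", "Brassicales"),
    d(3700L, 3699L, "family", "Brassicaceae"),
    d(3701L, 3700L, "genus", "Arabidopsis"),
    d(3702L, 3701L, "species", "Arabidopsis thaliana"),
    d(38820L, 3398L, "order", "Poales"),
    d(4479L, 38820L, "family", "Poaceae"),
    d(4527L, 4479L, "genus", "Oryza"),
    d(4530L, 4527L, "species", "Oryza sativa"),
    d(4890L, 2759L, "phylum", "Ascomycota"),
    d(4891L, 4890L, "class", "Saccharomycetes"),
    d(4892L, 4891L, "order", "Saccharomycetales"),
    d(4893L, 4892L, "family", "Saccharomycetaceae"),
    d(4930L, 4893L, "genus", "Saccharomyces"),
    d(4932L, 4930L, "species", "Saccharomyces cerevisiae")
  )
}

## species-rank rows of the fixture, used by the report simulator
fixture_species <- function() {
  tx <- fixture_taxa()
  tx[tx$rank == "species", c("taxid", "name")]
}

#' Write the packaged taxonomy fixture in NCBI taxdump layout
#'
#' Emits `nodes.dmp` and `names.dmp` (pipe-delimited dump dialect) for the
#' small synthetic taxonomy subset shipped with the package, so simulated
#' datasets are self-contained.
#'
#' @param dir output directory (created if missing).
#' @return named character vector with the two file paths.
#' @export
write_fixture_taxdump <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- fixture_taxa()
  nodes <- file.path(dir, "nodes.dmp")
  names_ <- file.path(dir, "names.dmp")
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", tx$taxid, tx$parent, tx$rank),
             nodes)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     tx$taxid, tx$name), names_)
  c(nodes = nodes, names = names_)
}

#' Paths to the installed taxonomy fixture files
#'
#' @return named character vector with elements `nodes` and `names`.
#' @export
taxdump_fixture_paths <- function() {
  c(nodes = system.file("extdata", "taxdump", "nodes.dmp",
                        package = "blastree", mustWork = TRUE),
    names = system.file("extdata", "taxdump", "names.dmp",
                        package = "blastree", mustWork = TRUE))
}
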