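# Taxdump loading, lineage queries, species resolution and taxon-based
# selection.

write_dmp <- function(nodes, names_) {
  dir <- tempfile(); dir.create(dir)
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(names_, file.path(dir, "names.dmp"))
  c(nodes = file.path(dir, "nodes.dmp"), names = file.path(dir, "names.dmp"))
}

test_that("a minimal taxdump loads and walks correctly", {
  p <- write_dmp(
    c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tsuperkingdom\t|",
      "562\t|\t2\t|\tspecies\t|"),
    c("1\t|\troot\t|\t\t|\tscientific name\t|",
      "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
      "562\t|\tEscherichia coli\t|\t\t|\tscientific name\t|",
      "562\t|\tE. coli\t|\t\t|\tsynonym\t|"))
  tx <- load_taxdump(p["nodes"], p["names"])
  expect_equal(nrow(tx$nodes), 3L)
  lin <- lineage(tx, 562)
  expect_equal(lin$name, c("root", "Bacteria", "Escherichia coli"))
  expect_equal(lineage(tx, 1)$name, "root")
  expect_error(lineage(tx, 999), "unknown taxid")
  ## synonyms are not indexed
  expect_false("E. coli" %in% names(tx$name2taxid))
})

test_that("orphan parents and cycles are integrity errors", {
  p <- write_dmp(
    c("1\t|\t1\t|\tno rank\t|", "2\t|\t999\t|\tphylum\t|"),
    c("1\t|\troot\t|\t\t|\tscientific name\t|",
      "2\t|\tX\t|\t\t|\tscientific name\t|"))
  expect_error(load_taxdump(p["nodes"], p["names"]), "orphan.*999")

  p <- write_dmp(
    c("1\t|\t1\t|\tno rank\t|", "2\t|\t3\t|\tphylum\t|",
      "3\t|\t2\t|\tclass\t|"),
    c("1\t|\troot\t|\t\t|\tscientific name\t|",
      "2\t|\tA\t|\t\t|\tscientific name\t|",
      "3\t|\tB\t|\t\t|\tscientific name\t|"))
  expect_error(load_taxdump(p["nodes"], p["names"]), "cycle")
})

test_that("reloading the packaged fixture is deterministic", {
  t1 <- load_fixture_taxonomy()
  t2 <- load_fixture_taxonomy()
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$name2taxid, t2$name2taxid)
})

test_that("lineages are prefix-closed and match a naive parent walk", {
  tx <- load_fixture_taxonomy()
  for (t in sample(tx$nodes$taxid, 20)) {
    lin <- lineage(tx, t)
    expect_equal(lin$taxid[1], tx$root)
    expect_equal(lin$taxid[nrow(lin)], t)
    ## naive walk oracle
    depth <- 1L; cur <- t
    while (cur != tx$root) {
      cur <- tx$nodes$parent[tx$nodes$taxid == cur]
      depth <- depth + 1L
    }
    expect_equal(nrow(lin), depth)
    ## prefix closure
    if (t != tx$root) {
      parent <- tx$nodes$parent[tx$nodes$taxid == t]
      expect_equal(lineage(tx, parent),
                   lin[-nrow(lin), ], ignore_attr = TRUE)
    }
  }
})

test_that("species resolution prefers taxid, then the last bracketed span", {
  tx <- load_fixture_taxonomy()
  mk <- function(desc, taxid = NA_integer_) {
    h <- make_truth_hit("H", "MKV", "MKV", 1L, 10, description = desc)
    hit <- new_blast_hit("H", description = desc, hsps = h$hsps,
                         taxid = taxid)
  }
  expect_equal(species_of_hit(mk("hypothetical protein [Escherichia coli]"),
                              tx),
               list(species = "Escherichia coli", taxid = 562L))
  expect_equal(species_of_hit(mk("no brackets here"), tx),
               list(species = "unknown", taxid = NA_integer_))
  ## two bracketed spans: the last one wins
  expect_equal(species_of_hit(
    mk("protein [fragment] [Homo sapiens]"), tx)$species, "Homo sapiens")
  ## explicit taxid beats the description
  expect_equal(species_of_hit(
    mk("whatever [Homo sapiens]", taxid = 562L), tx)$species,
    "Escherichia coli")
  ## unmatched bracket text degrades to unknown
  expect_equal(species_of_hit(mk("protein [Klingonia spuria]"), tx)$species,
               "unknown")
})

test_that("planted species are recovered for every simulated hit", {
  tx <- load_fixture_taxonomy()
  truth <- simulate_dataset(20, query_len = 60, sub_rate = 0.2, seed = 31)
  res <- annotate_hits(parse_truth(truth), tx)
  planted <- stats::setNames(
    vapply(truth$hits, `[[`, character(1), "species"),
    vapply(truth$hits, `[[`, character(1), "hit_id"))
  for (h in res$hits) expect_equal(h$species, planted[[h$hit_id]])
})

test_that("taxonomy summaries conserve hit counts at every depth", {
  tx <- load_fixture_taxonomy()
  truth <- simulate_dataset(25, query_len = 60, sub_rate = 0.2, seed = 17)
  res <- annotate_hits(parse_truth(truth), tx)
  check_node <- function(node) {
    if (length(node$children)) {
      kids <- sum(vapply(node$children, `[[`, integer(1), "count"))
      expect_lte(kids, node$count)
      for (k in node$children) check_node(k)
    }
    ## brute-force recount via lineage membership
    if (!is.na(node$taxid)) {
      n_direct <- sum(vapply(res$hits, function(h)
        !is.null(h$lineage) && node$taxid %in% h$lineage$taxid, logical(1)))
      expect_gte(n_direct, 0L)
    }
  }
  for (depth in c(1, 2, Inf)) {
    s <- taxonomy_summary(res, tx, max_depth = depth)
    expect_equal(s$count, length(res$hits))  # conservation at the root
    check_node(unclass(s))
    if (depth == 1) {
      for (k in s$children) expect_true(is.na(k$taxid) ||
        k$taxid %in% tx$nodes$taxid[tx$nodes$parent == tx$root])
    }
  }
  ## per-node counts equal brute-force lineage filtering (full depth)
  s <- taxonomy_summary(res, tx)
  walk <- function(node) {
    if (!is.na(node$taxid)) {
      brute <- sum(vapply(res$hits, function(h)
        !is.null(h$lineage) && node$taxid %in% h$lineage$taxid, logical(1)))
      expect_equal(node$count, brute)
    }
    for (k in node$children) walk(k)
  }
  walk(unclass(s))
  expect_match(format(s), "root")
})

test_that("unknown-taxonomy hits are grouped under a dedicated node", {
  tx <- load_fixture_taxonomy()
  truth <- make_truth(list(
    make_truth_hit("H1", "MKV", "MKV", 1L, 30, species = "Escherichia coli",
                   taxid = 562L),
    make_truth_hit("H2", "MKV", "MKA", 1L, 20, description = "mystery")),
    query_seq = "MKV")
  res <- annotate_hits(parse_truth(truth), tx)
  s <- taxonomy_summary(res, tx)
  expect_equal(s$count, 2L)
  kid_names <- vapply(s$children, `[[`, character(1), "name")
  expect_true("unknown" %in% kid_names)
  expect_equal(s$children[[which(kid_names == "unknown")]]$count, 1L)
})

get_hit_species <- function(res, label) {
  for (h in res$hits) if (h$hit_id == label) return(h$species)
  NA_character_
}

test_that("taxon selection partitions annotated hits", {
  tx <- load_fixture_taxonomy()
  truth <- simulate_dataset(17, query_len = 60, sub_rate = 0.2, seed = 23)
  res <- annotate_hits(parse_truth(truth), tx)
  bact <- select_by_taxon(res, tx, "Bacteria")
  truth_bact <- vapply(res$hits, function(h)
    "Bacteria" %in% h$lineage$name, logical(1))
  expect_setequal(bact, vapply(res$hits, `[[`, character(1),
                               "hit_id")[truth_bact])
  ## leaf species selects only that species' hits
  ecoli <- select_by_taxon(res, tx, "Escherichia coli")
  expect_true(all(vapply(ecoli, function(l)
    get_hit_species(res, l) == "Escherichia coli", logical(1))))
  ## include + exclude partition the annotated hits
  excl <- select_by_taxon(res, tx, "Bacteria", include = FALSE)
  annotated <- vapply(res$hits, function(h) !is.null(h$lineage), logical(1))
  expect_length(intersect(bact, excl), 0L)
  expect_setequal(union(bact, excl),
                  vapply(res$hits, `[[`, character(1), "hit_id")[annotated])
  ## numeric taxid works; unresolvable names list near-matches
  expect_setequal(select_by_taxon(res, tx, 2L), bact)
  expect_error(select_by_taxon(res, tx, "Escherichia colli"),
               "did you mean")
  expect_error(select_by_taxon(res, tx, 123456789), "unknown taxid")
})

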