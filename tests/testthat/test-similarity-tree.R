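# p-distances, neighbor joining (against two independent oracles), Newick
# serialization and leaf annotation.

msa_from_rows <- function(query_row, rows) {
  structure(list(column_count = nchar(query_row), query_label = "QUERY",
                 query_row = query_row, rows = rows, program = "blastp",
                 alphabet = "protein"), class = "pseudo_msa")
}

test_that("p-distances follow pairwise deletion in all-sites mode", {
  msa <- msa_from_rows("ACDE", c(r1 = "ACDE", r2 = "ACDK", r3 = "AC-E"))
  d <- p_distance_matrix(msa)
  expect_equal(unname(d["QUERY", "r1"]), 0)
  expect_equal(unname(d["QUERY", "r2"]), 0.25)  # 1 mismatch / 4 sites
  expect_equal(unname(d["QUERY", "r3"]), 0)     # 3 compared, 0 mismatches
  expect_equal(unname(d["r2", "r3"]), 1 / 3)
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))
})

test_that("gap-free mode uses only columns without any gap", {
  msa <- msa_from_rows("ACDE", c(r1 = "AC-E", r2 = "GCDE"))
  d <- p_distance_matrix(msa, site_mode = "gap_free")
  ## columns 1, 2, 4 survive; r1 vs r2 differ at column 1 only
  expect_equal(unname(d["r1", "r2"]), 1 / 3)
  allgap <- msa_from_rows("ACDE", c(r1 = "AC--", r2 = "--DE"))
  expect_error(p_distance_matrix(allgap, site_mode = "gap_free"),
               "all_sites")
})

test_that("rows sharing no columns get distance 1 with a warning", {
  msa <- msa_from_rows("ACDE", c(r1 = "AC--", r2 = "--DE"))
  expect_warning(d <- p_distance_matrix(msa, c("r1", "r2")),
                 "no comparable")
  expect_equal(unname(d["r1", "r2"]), 1)
})

test_that("distance validation rejects degenerate input", {
  msa <- msa_from_rows("ACDE", c(r1 = "ACDE"))
  expect_error(p_distance_matrix(msa, "r1"), "two rows")
  bad <- matrix(c(0, 0.1, 0.3, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- matrix(c(0, -0.1, -0.1, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(neg), "negative")
})

test_that("NJ recovers the generating additive four-leaf tree exactly", {
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4, dimnames = list(labs, labs))
  tree <- neighbor_joining(d)
  expect_equal(tree$clamp_deficit, 0)
  ref <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5));")
  expect_equal(rf_dist(tree$phylo, ref), 0)
  got <- stats::cophenetic(tree$phylo)[labs, labs]
  expect_equal(got, d, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("three leaves resolve by the closed-form three-point formulas", {
  labs <- c("A", "B", "C")
  d <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
              dimnames = list(labs, labs))
  tree <- neighbor_joining(d)
  expect_equal(to_newick(tree), "(A:0.1,B:0.2,C:0.4);")
})

test_that("two leaves split their distance in half", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(to_newick(neighbor_joining(d)), "(A:0.2,B:0.2);")
})

test_that("NJ matches an independently coded textbook NJ for n <= 6", {
  set.seed(42)
  for (k in 1:25) {
    n <- sample(4:6, 1)
    ra <- random_additive(n)
    D <- ra$D
    if (k %% 2 == 0) {  # perturbed (non-additive) matrices too
      noise <- matrix(stats::runif(n * n, 0, 0.05), n)
      noise <- (noise + t(noise)) / 2; diag(noise) <- 0
      D <- D + noise
    }
    mine <- neighbor_joining(D)
    ref <- ape::read.tree(text = naive_nj_newick(D))
    expect_equal(rf_dist(mine$phylo, ref), 0)
    expect_equal(sort(mine$phylo$edge.length), sort(ref$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("NJ recovers random additive trees with exact edge lengths", {
  set.seed(7)
  for (k in 1:30) {
    ra <- random_additive(sample(5:9, 1))
    tree <- neighbor_joining(ra$D)
    expect_equal(rf_dist(tree$phylo, ra$tree), 0)
    expect_equal(tree$clamp_deficit, 0)  # clamping never fires on additive
    got <- stats::cophenetic(tree$phylo)[rownames(ra$D), rownames(ra$D)]
    expect_equal(got, ra$D, tolerance = 1e-9, ignore_attr = TRUE)
    ## independent cross-check against ape's NJ topology
    expect_equal(rf_dist(tree$phylo, ape::nj(stats::as.dist(ra$D))), 0)
  }
})

test_that("exhaustive least-squares topology search agrees with NJ", {
  set.seed(99)
  for (k in 1:6) {
    n <- sample(5:6, 1)
    ra <- random_additive(n)
    labs <- rownames(ra$D)
    idx <- match(labs, labs)  # leaves numbered in matrix order
    fits <- lapply(all_topologies(n), ls_fit_topology, D = ra$D, labs = labs)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
    expect_lt(best$rss, 1e-12)  # additive: the true topology fits exactly
    expect_equal(rf_dist(ape::read.tree(text = best$newick),
                         neighbor_joining(ra$D)$phylo), 0)
  }
})

test_that("Newick output sanitizes labels and round-trips", {
  d <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  rownames(d) <- colnames(d) <- c("E. coli (K12)", "Homo sapiens")
  nwk <- to_newick(neighbor_joining(d))
  expect_equal(nwk, "(E._coli_K12:0.1,Homo_sapiens:0.1);")

  set.seed(3)
  for (k in 1:10) {
    ra <- random_additive(sample(4:8, 1))
    tree <- neighbor_joining(ra$D)
    reparsed <- ape::read.tree(text = to_newick(tree))
    expect_equal(rf_dist(tree$phylo, reparsed), 0)
    expect_equal(sort(reparsed$edge.length), sort(tree$phylo$edge.length),
                 tolerance = 1e-9)
  }
})

## --- annotation ----------------------------------------------------------

annotated_result <- function(n = 6, seed = 2) {
  truth <- simulate_dataset(n, query_len = 80, sub_rate = 0.1, seed = seed)
  res <- parse_truth(truth)
  annotate_hits(res, load_fixture_taxonomy())
}

test_that("leaves are renamed by species with accession suffix on collision", {
  truth <- make_truth(list(
    make_truth_hit("H1", "MKVLQRAA", "MKVLQRAA", 1L, 40, accession = "ACC1",
                   species = "Escherichia coli", taxid = 562L),
    make_truth_hit("H2", "MKVLQRAA", "MKVLQRCA", 1L, 30, accession = "ACC2",
                   species = "Escherichia coli", taxid = 562L),
    make_truth_hit("H3", "MKVLQRAA", "MKVLQKCA", 1L, 20, accession = "ACC3",
                   species = "Homo sapiens", taxid = 9606L)),
    query_seq = "MKVLQRAA")
  res <- annotate_hits(parse_truth(truth), load_fixture_taxonomy())
  tree <- rebuild_tree(res)
  labs <- tree$phylo$tip.label
  expect_true(all(c("Escherichia_coli_ACC1", "Escherichia_coli_ACC2",
                    "Homo_sapiens") %in% labs))
  expect_true("QUERY" %in% labs)
})

test_that("hits without taxonomy fall into the unknown group", {
  truth <- make_truth(list(
    make_truth_hit("H1", "MKVLQRAA", "MKVLQRAA", 1L, 40,
                   species = "Nonexistium fake", taxid = NA_integer_,
                   description = "mystery protein")),
    query_seq = "MKVLQRAA")
  res <- annotate_hits(parse_truth(truth), load_fixture_taxonomy())
  tree <- rebuild_tree(res)
  ann <- tree$annotations
  expect_equal(ann$group[ann$hit_id == "H1"], "unknown")
  expect_equal(ann$species[ann$hit_id == "H1"], "unknown")
})

test_that("rank-level grouping yields one color group per lineage name", {
  ## fixture species cycle covers three phyla in the first three hits:
  ## Proteobacteria (E. coli, S. enterica, Y. pestis...) depends on pool
  res <- annotated_result(n = 6, seed = 5)
  tree <- rebuild_tree(res, rank = "phylum")
  ann <- tree$annotations
  hit_groups <- ann$group[ann$hit_id != "QUERY"]
  lineages <- lapply(res$hits, `[[`, "lineage")
  expected <- vapply(lineages, function(l) {
    i <- which(l$rank == "phylum"); if (length(i)) l$name[i] else "unknown"
  }, character(1))
  expect_setequal(unique(hit_groups), unique(expected))
  ## one color per group
  expect_equal(length(unique(ann$color)), length(unique(ann$group)))
  ## superkingdom regrouping changes group count accordingly
  tree2 <- rebuild_tree(res, rank = "superkingdom")
  expected2 <- vapply(lineages, function(l) {
    i <- which(l$rank == "superkingdom")
    if (length(i)) l$name[i] else "unknown"
  }, character(1))
  expect_setequal(unique(tree2$annotations$group[
    tree2$annotations$hit_id != "QUERY"]), unique(expected2))
})

test_that("a leaf with no matching hit is an error", {
  res <- annotated_result()
  d <- matrix(0.1, 3, 3); diag(d) <- 0
  rownames(d) <- colnames(d) <- c("QUERY", "HIT_0001", "GHOST")
  tree <- neighbor_joining(d)
  expect_error(annotate_and_name(tree, res), "GHOST")
})

test_that("rebuilding keeps the query and the selected leaf set", {
  res <- annotated_result(n = 8, seed = 6)
  sel <- hit_feature_table(res)$hit_id[1:5]
  t1 <- rebuild_tree(res, selection = sel)
  expect_equal(length(t1$phylo$tip.label), 6L)  # query always included
  t2 <- rebuild_tree(res, selection = sel, site_mode = "gap_free")
  expect_setequal(t2$annotations$hit_id, t1$annotations$hit_id)
  expect_error(rebuild_tree(res, selection = character(0)), "empty")
})
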