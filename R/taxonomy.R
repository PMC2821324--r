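# Local taxonomy support: loading an NCBI taxdump-style table, lineage
# queries, species resolution for hits, hierarchical summaries and
# taxon-based hit selection.

#' Load an NCBI taxdump-style taxonomy table
#'
#' Reads `nodes.dmp` / `names.dmp` in the pipe-delimited NCBI dump layout.
#' Only `scientific name` entries of the names file are indexed, so the
#' name-to-taxid index stays unambiguous.  Orphan parents and cycles are
#' integrity errors.
#'
#' @param nodes_path path to `nodes.dmp` (taxid | parent | rank | ...).
#' @param names_path path to `names.dmp` (taxid | name | unique | class |).
#' @return an object of class `taxonomy_table`.
#' @export
load_taxdump <- function(nodes_path, names_path) {
  split_dmp <- function(path) {
    lines <- readLines(path)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nd <- split_dmp(nodes_path)
  taxid <- vapply(nd, function(x) as.integer(x[1]), integer(1))
  parent <- vapply(nd, function(x) as.integer(x[2]), integer(1))
  rank <- vapply(nd, function(x) x[3], character(1))
  if (anyDuplicated(taxid))
    stop_blastree("duplicate taxid in nodes file: ",
                  taxid[duplicated(taxid)][1])

  nm <- split_dmp(names_path)
  keep <- vapply(nm, function(x) length(x) >= 4 && x[4] == "scientific name",
                 logical(1))
  nm <- nm[keep]
  nm_taxid <- vapply(nm, function(x) as.integer(x[1]), integer(1))
  nm_name <- vapply(nm, function(x) x[2], character(1))
  name <- nm_name[match(taxid, nm_taxid)]
  name[is.na(name)] <- sprintf("taxid_%d", taxid[is.na(name)])

  roots <- taxid[taxid == parent]
  if (length(roots) != 1L)
    stop_blastree("taxonomy must have exactly one root (taxid == parent); found ",
                  length(roots))
  orphan <- setdiff(parent, taxid)
  if (length(orphan))
    stop_blastree("orphan parent taxid in nodes file: ",
                  paste(orphan, collapse = ", "))

  ## cycle check: every walk must reach the root in <= n steps
  parent_of <- structure(parent, names = as.character(taxid))
  n <- length(taxid)
  for (t in taxid) {
    cur <- t; steps <- 0L
    while (cur != roots) {
      cur <- parent_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n)
        stop_blastree("cycle in taxonomy involving taxid ", t)
    }
  }

  nodes <- data.frame(taxid = taxid, parent = parent, rank = rank,
                      name = name, stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes,
    parent_of = parent_of,
    rank_of = structure(rank, names = as.character(taxid)),
    name_of = structure(name, names = as.character(taxid)),
    name2taxid = structure(taxid, names = name),
    root = roots
  ), class = "taxonomy_table")
}

#' Load the packaged taxonomy fixture
#'
#' @return a `taxonomy_table` built from the installed fixture files.
#' @export
load_fixture_taxonomy <- function() {
  p <- taxdump_fixture_paths()
  load_taxdump(p[["nodes"]], p[["names"]])
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat(sprintf("<taxonomy_table> %d taxa, root taxid %d\n",
              nrow(x$nodes), x$root))
  invisible(x)
}

#' Lineage of a taxon, root first
#'
#' @param table a `taxonomy_table`.
#' @param taxid taxid present in the table.
#' @return data.frame with columns `taxid`, `rank`, `name`, ordered from the
#'   root down to the queried taxon.
#' @export
lineage <- function(table, taxid) {
  key <- as.character(taxid)
  if (!key %in% names(table$parent_of))
    stop_blastree("unknown taxid: ", taxid)
  path <- integer(0)
  cur <- as.integer(taxid)
  repeat {
    path <- c(cur, path)
    if (cur == table$root) break
    cur <- table$parent_of[[as.character(cur)]]
  }
  data.frame(taxid = path,
             rank = unname(table$rank_of[as.character(path)]),
             name = unname(table$name_of[as.character(path)]),
             stringsAsFactors = FALSE)
}

#' Resolve the species of a hit
#'
#' Uses the hit's `taxid` when it is present and known to the table;
#' otherwise the last bracketed `[...]` span of the description (the NR
#' convention for organism names) is matched against the scientific-name
#' index.  Unresolvable hits degrade to `"unknown"` rather than erroring.
#'
#' @param hit a `blast_hit`.
#' @param table a `taxonomy_table`.
#' @return list with elements `species` (character) and `taxid`
#'   (integer, `NA` when unresolved).
#' @export
species_of_hit <- function(hit, table) {
  if (!is.na(hit$taxid) && as.character(hit$taxid) %in% names(table$name_of))
    return(list(species = unname(table$name_of[[as.character(hit$taxid)]]),
                taxid = as.integer(hit$taxid)))
  spans <- regmatches(hit$description,
                      gregexpr("\\[([^][]*)\\]", hit$description))[[1]]
  if (length(spans)) {
    cand <- sub("^\\[", "", sub("\\]$", "", spans[length(spans)]))
    if (cand %in% names(table$name2taxid))
      return(list(species = cand,
                  taxid = unname(table$name2taxid[[cand]])))
  }
  list(species = "unknown", taxid = NA_integer_)
}

#' Attach species, taxid and lineage to every hit
#'
#' @param result a `blast_result`.
#' @param table a `taxonomy_table`.
#' @return the annotated `blast_result`.
#' @export
annotate_hits <- function(result, table) {
  result$hits <- lapply(result$hits, function(h) {
    sp <- species_of_hit(h, table)
    h$species <- sp$species
    h$taxid <- sp$taxid
    h$lineage <- if (!is.na(sp$taxid)) lineage(table, sp$taxid) else NULL
    h
  })
  result
}

## lineage name at a given rank, or "unknown"
lineage_at_rank <- function(lin, rank) {
  if (is.null(lin)) return("unknown")
  i <- which(lin$rank == rank)
  if (length(i)) lin$name[i[1]] else "unknown"
}

#' Hierarchical taxonomy summary of a hit list
#'
#' Counts hits per taxon as a nested tree down to `max_depth` levels below
#' the root.  Each node's count equals the sum of its children's counts plus
#' the hits assigned exactly at that node; hits without taxonomy are grouped
#' under a dedicated `unknown` child of the root.
#'
#' @param result a `blast_result` whose hits carry lineages
#'   (see [annotate_hits()]).
#' @param table a `taxonomy_table`.
#' @param max_depth maximum number of levels below the root (default all).
#' @return nested list (`name`, `taxid`, `rank`, `count`, `children`) of
#'   class `taxonomy_summary`.
#' @export
taxonomy_summary <- function(result, table, max_depth = Inf) {
  paths <- lapply(result$hits, function(h) {
    if (is.null(h$lineage)) return(NULL)
    p <- h$lineage$taxid
    if (is.finite(max_depth)) p <- p[seq_len(min(length(p), max_depth + 1L))]
    p
  })
  n_unknown <- sum(vapply(paths, is.null, logical(1)))
  paths <- paths[!vapply(paths, is.null, logical(1))]

  build <- function(taxid, paths_here, depth) {
    ## paths_here: lineage paths (vectors) all of which contain `taxid` at
    ## position `depth`
    here <- vapply(paths_here, function(p) length(p) == depth, logical(1))
    deeper <- paths_here[!here]
    kids <- list()
    if (length(deeper)) {
      nxt <- vapply(deeper, function(p) p[depth + 1L], numeric(1))
      for (child in unique(nxt))
        kids[[length(kids) + 1L]] <-
          build(child, deeper[nxt == child], depth + 1L)
    }
    list(name = unname(table$name_of[[as.character(taxid)]]),
         taxid = as.integer(taxid),
         rank = unname(table$rank_of[[as.character(taxid)]]),
         count = length(paths_here),
         children = kids)
  }
  root <- build(table$root, paths, 1L)
  root$count <- root$count + n_unknown
  if (n_unknown > 0L)
    root$children[[length(root$children) + 1L]] <-
      list(name = "unknown", taxid = NA_integer_, rank = "no rank",
           count = n_unknown, children = list())
  structure(root, class = "taxonomy_summary")
}

#' @export
format.taxonomy_summary <- function(x, ...) {
  out <- character(0)
  walk <- function(node, indent) {
    out <<- c(out, sprintf("%s%s (%s): %d", strrep("  ", indent),
                           node$name, node$rank, node$count))
    for (k in node$children) walk(k, indent + 1L)
  }
  walk(unclass(x), 0L)
  paste(out, collapse = "\n")
}

#' @export
print.taxonomy_summary <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Select hits by taxon
#'
#' With `include = TRUE`, returns the hits whose lineage contains the taxon;
#' with `include = FALSE` the complement among taxonomy-annotated hits.
#' Hits without taxonomy never match an inclusive selection.
#'
#' @param result an annotated `blast_result`.
#' @param table a `taxonomy_table`.
#' @param taxon a taxid or a scientific name.
#' @param include include (`TRUE`) or exclude (`FALSE`) the clade.
#' @return character vector of hit labels.
#' @export
select_by_taxon <- function(result, table, taxon, include = TRUE) {
  if (is.numeric(taxon)) {
    if (!as.character(taxon) %in% names(table$name_of))
      stop_blastree("unknown taxid: ", taxon)
    target <- as.integer(taxon)
  } else {
    if (!taxon %in% names(table$name2taxid)) {
      near <- utils::head(agrep(taxon, names(table$name2taxid),
                                max.distance = 0.3, value = TRUE), 5L)
      stop_blastree("unresolvable taxon '", taxon, "'",
                    if (length(near))
                      paste0("; did you mean: ",
                             paste(near, collapse = ", "), "?"))
    }
    target <- table$name2taxid[[taxon]]
  }
  annotated <- vapply(result$hits, function(h) !is.null(h$lineage), logical(1))
  matches <- vapply(result$hits, function(h)
    !is.null(h$lineage) && target %in% h$lineage$taxid, logical(1))
  ids <- hit_ids(result)
  if (include) ids[matches] else ids[annotated & !matches]
}
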