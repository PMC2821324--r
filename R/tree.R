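# The similarity tree: an unrooted NJ p-distance tree over the query and
# the selected hits, with species-renamed, taxonomy-grouped leaves.  It is a
# triage aid — fast and robust enough to show approximate relationships —
# not a publication-grade phylogeny.

## fixed qualitative palette, cycled over taxonomy groups in order of first
## appearance
GROUP_PALETTE <- c(
  "#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e", "#e6ab02",
  "#a6761d", "#666666", "#1f78b4", "#b2df8a", "#fb9a99", "#cab2d6",
  "#ff7f00", "#6a3d9a", "#b15928", "#8dd3c7", "#bebada", "#fb8072",
  "#80b1d3", "#fdb462")

new_similarity_tree <- function(phylo, site_mode = NA_character_,
                                clamp_deficit = 0, annotations = NULL) {
  if (is.null(annotations))
    annotations <- data.frame(
      label = phylo$tip.label, hit_id = phylo$tip.label,
      species = NA_character_, taxid = NA_integer_,
      group = NA_character_, color = NA_character_,
      coverage = NA_real_, description = NA_character_,
      stringsAsFactors = FALSE)
  structure(list(phylo = phylo, annotations = annotations,
                 site_mode = site_mode, clamp_deficit = clamp_deficit),
            class = "similarity_tree")
}

#' @export
print.similarity_tree <- function(x, ...) {
  ngrp <- length(unique(stats::na.omit(x$annotations$group)))
  cat(sprintf("<similarity_tree> %d leaves%s%s\n",
              length(x$phylo$tip.label),
              if (!is.na(x$site_mode)) paste0(", site mode ", x$site_mode)
              else "",
              if (ngrp) paste0(", ", ngrp, " taxonomy group(s)") else ""))
  invisible(x)
}

#' Rename and annotate the leaves of a similarity tree
#'
#' Leaves are renamed to their species name (underscored); when two or more
#' leaves share a species, each gets its accession as a suffix.  Every leaf
#' is assigned a taxonomy group — its lineage name at the requested rank, or
#' `"unknown"` — and a stable color per group (palette cycled in order of
#' first appearance).  The query leaf keeps the query label.
#'
#' @param tree a `similarity_tree` whose tip labels are hit labels (plus
#'   optionally the query).
#' @param result the `blast_result` the tree was built from, with taxonomy
#'   annotation (see [annotate_hits()]).
#' @param rank taxonomic rank used for grouping/coloring (default
#'   `"phylum"`).
#' @return the annotated `similarity_tree`.
#' @export
annotate_and_name <- function(tree, result, rank = "phylum") {
  tips <- tree$phylo$tip.label
  ids <- hit_ids(result)
  is_query <- tips == result$query_id
  unknown_tip <- !is_query & !(tips %in% ids)
  if (any(unknown_tip))
    stop_blastree("leaf/leaves with no matching hit: ",
                  paste(tips[unknown_tip], collapse = ", "))

  ann <- data.frame(label = tips, hit_id = tips, species = NA_character_,
                    taxid = NA_integer_, group = NA_character_,
                    color = NA_character_, coverage = NA_real_,
                    description = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(tips)) {
    if (is_query[k]) {
      ann$species[k] <- "query"; ann$group[k] <- "query"
      ann$coverage[k] <- 1; ann$description[k] <- result$query_def
      next
    }
    h <- get_hit(result, tips[k])
    ann$species[k] <- if (is.na(h$species)) "unknown" else h$species
    ann$taxid[k] <- h$taxid
    ann$group[k] <- lineage_at_rank(h$lineage, rank)
    ann$coverage[k] <- coverage_of_hit(h, result$query_len, result$program)
    ann$description[k] <- h$description
  }

  ## species-based renaming with accession suffix on collisions
  new_label <- tips
  for (k in which(!is_query)) {
    sp <- ann$species[k]
    if (identical(sp, "unknown")) next
    dup <- sum(ann$species[!is_query] == sp) > 1L
    h <- get_hit(result, tips[k])
    new_label[k] <- sanitize_label(
      if (dup) paste(sp, h$accession) else sp)
  }
  new_label <- make.unique(new_label, sep = "_")
  ann$label <- new_label
  tree$phylo$tip.label <- new_label

  groups <- unique(ann$group)
  ann$color <- GROUP_PALETTE[((match(ann$group, groups) - 1L) %%
                                length(GROUP_PALETTE)) + 1L]
  tree$annotations <- ann
  tree
}

#' Serialize a similarity tree to Newick
#'
#' Branch lengths at full precision; labels sanitized (spaces to
#' underscores, structural characters stripped).  The string re-parses
#' (e.g. with `ape::read.tree`) to an isomorphic topology.
#'
#' @param tree a `similarity_tree` or an `ape::phylo` object.
#' @return a single Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree) {
  phy <- if (inherits(tree, "similarity_tree")) tree$phylo else tree
  n <- length(phy$tip.label)
  labs <- sanitize_label(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  rec <- function(node) {
    if (node <= n) return(labs[node])
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(k)
      paste0(rec(phy$edge[k, 2L]), ":", fmt(phy$edge.length[k])),
      character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(n + 1L), ";")
}

#' Write a similarity tree as a Newick file
#' @param tree a `similarity_tree`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}

#' Write the leaf annotation sidecar as TSV
#' @param tree an annotated `similarity_tree`.
#' @param path output path.
#' @export
write_tree_annotations <- function(tree, path) {
  utils::write.table(tree$annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build (or rebuild) the similarity tree for a selection
#'
#' Composes [p_distance_matrix()], [neighbor_joining()] and
#' [annotate_and_name()] over the current selection plus the query.  The
#' default build — no explicit selection — uses the top-100 scoring hits and
#' all sites, the initial view of the result page.
#'
#' @param result a `blast_result` (taxonomy-annotated if group coloring is
#'   wanted).
#' @param msa optional precomputed `pseudo_msa` for `result` (built on the
#'   fly otherwise).
#' @param selection character vector of selected hit labels; `NULL` means
#'   the top-`top_n` hits.  Must be non-empty when supplied.
#' @param site_mode `"all_sites"` or `"gap_free"`.
#' @param top_n size of the default selection (default 100).
#' @param rank taxonomic rank for leaf grouping.
#' @return an annotated `similarity_tree`; the query is always a leaf.
#' @export
rebuild_tree <- function(result, msa = NULL, selection = NULL,
                         site_mode = c("all_sites", "gap_free"),
                         top_n = 100L, rank = "phylum") {
  site_mode <- match.arg(site_mode)
  if (is.null(selection)) {
    selection <- top_n_hits(result, top_n)
  } else if (length(selection) == 0L) {
    stop_blastree("selection is empty")
  }
  if (is.null(msa)) msa <- stack_hsps(result)
  d <- p_distance_matrix(msa, labels = c(result$query_id, selection),
                         site_mode = site_mode)
  tree <- neighbor_joining(d)
  annotate_and_name(tree, result, rank = rank)
}

#' Plot a similarity tree
#'
#' Unrooted NJ tree drawn with `ape`, tips colored by taxonomy group.
#'
#' @param x an annotated `similarity_tree`.
#' @param type plot type passed to `ape::plot.phylo`.
#' @param cex tip label size.
#' @param ... further arguments to `ape::plot.phylo`.
#' @export
plot.similarity_tree <- function(x, type = "phylogram", cex = 0.7, ...) {
  col <- x$annotations$color[match(x$phylo$tip.label, x$annotations$label)]
  col[is.na(col)] <- "black"
  ape::plot.phylo(x$phylo, type = type, tip.color = col, cex = cex, ...)
  invisible(x)
}
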