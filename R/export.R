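# FASTA export of selected hits and the end-to-end pipeline runner behind
# the command-line front end.

#' Export selected hits as FASTA
#'
#' One record per selected hit.  BLAST XML reports carry only the aligned
#' HSP segments, not full subject records, so by default each sequence is
#' the ungapped concatenation of the hit's kept HSP segments (in subject
#' order) and the header is flagged `partial`.  Supplying the subject
#' database as FASTA (`subject_fasta`) substitutes the full sequences.
#'
#' @param result a `blast_result`.
#' @param labels non-empty character vector of selected hit labels.
#' @param path output path.
#' @param subject_fasta optional FASTA whose record identifiers (first
#'   header word) match hit labels; provides full sequences.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(result, labels, path, subject_fasta = NULL) {
  if (length(labels) == 0L) stop_blastree("empty selection: nothing to export")
  subjects <- NULL
  if (!is.null(subject_fasta)) {
    ss <- Biostrings::readBStringSet(subject_fasta)
    subjects <- stats::setNames(as.character(ss),
                                sub("\\s.*", "", names(ss)))
  }
  lines <- unlist(lapply(labels, function(l) {
    h <- get_hit(result, l)
    species <- if (is.na(h$species)) "unknown" else h$species
    if (!is.null(subjects) && l %in% names(subjects)) {
      seq <- subjects[[l]]
      flag <- ""
    } else {
      kept <- resolve_hsps(h, result$program)
      ord <- order(vapply(kept, `[[`, integer(1), "hit_start"))
      seq <- paste(vapply(kept[ord], function(p) ungap(p$aligned_hit),
                          character(1)), collapse = "")
      flag <- " partial"
    }
    c(sprintf(">%s %s [%s] %s%s", l, h$accession, species,
              h$description, flag), seq)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Run configuration for the pipeline
#'
#' @param blast_xml path to the BLAST XML report.
#' @param query_fasta optional query FASTA.
#' @param taxdump_nodes,taxdump_names optional taxonomy dump paths.
#' @param subject_fasta optional subject database FASTA for full-sequence
#'   export.
#' @param out_dir output directory.
#' @param state a [selection_state()] (thresholds, intervals, taxa, top-N,
#'   site mode).
#' @param rank taxonomic rank for tree coloring.
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return an object of class `run_config`.
#' @export
run_config <- function(blast_xml, query_fasta = NULL,
                       taxdump_nodes = NULL, taxdump_names = NULL,
                       subject_fasta = NULL, out_dir = ".",
                       state = selection_state(), rank = "phylum",
                       seed = 1L) {
  for (p in c(blast_xml, query_fasta, taxdump_nodes, taxdump_names,
              subject_fasta))
    if (!is.null(p) && !file.exists(p))
      stop_blastree("input path does not exist: ", p)
  structure(list(blast_xml = blast_xml, query_fasta = query_fasta,
                 taxdump_nodes = taxdump_nodes,
                 taxdump_names = taxdump_names,
                 subject_fasta = subject_fasta, out_dir = out_dir,
                 state = state, rank = rank, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a run configuration to a flat key=value file
#' @param config a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  kv <- function(k, v) if (is.null(v)) character(0) else paste0(k, "=", v)
  lines <- c(
    kv("blast_xml", config$blast_xml),
    kv("query_fasta", config$query_fasta),
    kv("taxdump_nodes", config$taxdump_nodes),
    kv("taxdump_names", config$taxdump_names),
    kv("subject_fasta", config$subject_fasta),
    kv("out_dir", config$out_dir),
    kv("rank", config$rank),
    kv("seed", config$seed),
    kv("e_value", format(config$state$e_value, digits = 15)),
    kv("top_n", config$state$top_n),
    kv("site_mode", config$state$site_mode),
    vapply(config$state$intervals, function(iv)
      sprintf("interval=%s:%s:%s", iv$metric,
              format(iv$low, digits = 15), format(iv$high, digits = 15)),
      character(1)),
    vapply(config$state$taxa, function(tx)
      sprintf("taxon=%s:%s", tx$taxon,
              if (isTRUE(tx$include)) "include" else "exclude"),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration
#' @param path file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  key <- sub("=.*", "", lines)
  val <- sub("^[^=]*=", "", lines)
  pick <- function(k) if (k %in% key) val[key == k][1L] else NULL
  intervals <- lapply(val[key == "interval"], function(x) {
    p <- strsplit(x, ":", fixed = TRUE)[[1L]]
    list(metric = p[1L], low = as.numeric(p[2L]), high = as.numeric(p[3L]))
  })
  taxa <- lapply(val[key == "taxon"], function(x) {
    p <- strsplit(x, ":", fixed = TRUE)[[1L]]
    list(taxon = p[1L], include = identical(p[2L], "include"))
  })
  state <- selection_state(
    e_value = if (is.null(pick("e_value"))) Inf
              else as.numeric(pick("e_value")),
    intervals = intervals, taxa = taxa,
    top_n = as.integer(pick("top_n") %||% 100L),
    site_mode = pick("site_mode") %||% "all_sites")
  run_config(blast_xml = pick("blast_xml"),
             query_fasta = pick("query_fasta"),
             taxdump_nodes = pick("taxdump_nodes"),
             taxdump_names = pick("taxdump_names"),
             subject_fasta = pick("subject_fasta"),
             out_dir = pick("out_dir") %||% ".",
             state = state, rank = pick("rank") %||% "phylum",
             seed = as.integer(pick("seed") %||% 1L))
}

#' Run the whole post-processing pipeline
#'
#' Parses the report, attaches taxonomy, applies the configured filters
#' (logging before/after hit counts for each), takes the top-N view, builds
#' the similarity tree and writes the output bundle: `tree.nwk`,
#' `annotations.tsv`, `features.tsv`, `selected.fasta` and `run.log`.
#' Deterministic for a given configuration.
#'
#' @param config a `run_config` or the path to one.
#' @return named character vector of output paths, invisibly; the
#'   `summary` attribute carries hit counts per stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", "blastree", sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  set.seed(config$seed)
  logmsg("parsing %s", config$blast_xml)
  result <- parse_blast_xml(config$blast_xml,
                            query_fasta = config$query_fasta)
  logmsg("parsed %d hits (query %s, %d residues)", length(result$hits),
         result$query_id, result$query_len)

  taxonomy <- NULL
  if (!is.null(config$taxdump_nodes) && !is.null(config$taxdump_names)) {
    taxonomy <- load_taxdump(config$taxdump_nodes, config$taxdump_names)
    result <- annotate_hits(result, taxonomy)
    logmsg("taxonomy attached (%d taxa)", nrow(taxonomy$nodes))
  }

  state <- config$state
  sel <- hit_ids(result)
  if (is.finite(state$e_value)) {
    after <- intersect(sel, apply_evalue_threshold(result, state$e_value))
    logmsg("filter e_value<=%g: %d -> %d hits", state$e_value,
           length(sel), length(after))
    sel <- after
  }
  for (iv in state$intervals) {
    after <- intersect(sel, select_interval(result, iv$metric, iv$low,
                                            iv$high))
    logmsg("filter %s in [%g, %g]: %d -> %d hits", iv$metric, iv$low,
           iv$high, length(sel), length(after))
    sel <- after
  }
  for (tx in state$taxa) {
    after <- intersect(sel, select_by_taxon(result, taxonomy, tx$taxon,
                                            include = isTRUE(tx$include)))
    logmsg("filter taxon %s (%s): %d -> %d hits", tx$taxon,
           if (isTRUE(tx$include)) "include" else "exclude",
           length(sel), length(after))
    sel <- after
  }
  shown <- top_n_hits(result, state$top_n, within = sel)
  logmsg("top-%d view: %d hit(s) shown", state$top_n, length(shown))
  if (length(shown) == 0L)
    stop_blastree("no hits pass the configured filters")

  msa <- stack_hsps(result)
  tree <- rebuild_tree(result, msa = msa, selection = shown,
                       site_mode = state$site_mode, rank = config$rank)
  logmsg("similarity tree: %d leaves, site mode %s, gap-free sites %d",
         length(tree$phylo$tip.label), state$site_mode,
         gap_free_site_count(msa, shown))

  out <- c(tree = file.path(config$out_dir, "tree.nwk"),
           annotations = file.path(config$out_dir, "annotations.tsv"),
           features = file.path(config$out_dir, "features.tsv"),
           fasta = file.path(config$out_dir, "selected.fasta"),
           log = file.path(config$out_dir, "run.log"))
  write_newick(tree, out[["tree"]])
  write_tree_annotations(tree, out[["annotations"]])
  write_feature_table(hit_feature_table(result), out[["features"]])
  export_fasta(result, shown, out[["fasta"]],
               subject_fasta = config$subject_fasta)
  writeLines(log_lines, out[["log"]])
  attr(out, "summary") <- list(n_parsed = length(result$hits),
                               n_selected = length(sel),
                               n_shown = length(shown))
  invisible(out)
}
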