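# Hit-selection model: per-hit metrics (coverage, pooled percent
# similarity), E-value thresholding, metric distributions with interval
# selection, and the top-N view.  All filters are pure functions from a
# result to a label set and compose as set intersection, so applying them in
# any order yields the same selection.

#' Query coverage of a hit
#'
#' Fraction of query positions covered by the union of the hit's kept
#' (post-[resolve_hsps()]) HSP query intervals.
#'
#' @param hit a `blast_hit`.
#' @param query_len query length in residues.
#' @param program BLAST program (frame handling for blastx).
#' @return fraction in `[0, 1]`.
#' @export
coverage_of_hit <- function(hit, query_len, program = "blastp") {
  kept <- resolve_hsps(hit, program)
  iv <- do.call(rbind, lapply(kept, function(h)
    hsp_query_columns(h, program, query_len)))
  W <- if (identical(program, "blastx")) {
    f <- kept[[1L]]$query_frame
    (query_len - abs(f) + 1L) %/% 3L
  } else query_len
  interval_union_length(iv) / W
}

#' Pooled percent similarity of a hit
#'
#' `100 * sum(positives) / sum(align_len)` over the kept HSPs
#' (length-weighted pooling, not a per-HSP average); for blastn, identities
#' stand in for positives.
#'
#' @param hit a `blast_hit`.
#' @param program BLAST program.
#' @return percentage in `[0, 100]`.
#' @export
percent_similarity_of_hit <- function(hit, program = "blastp") {
  kept <- resolve_hsps(hit, program)
  num_field <- if (identical(program, "blastn")) "identities" else "positives"
  num <- sum(vapply(kept, function(h) {
    v <- h[[num_field]]
    if (is.na(v)) h$identities else v
  }, numeric(1)))
  den <- sum(vapply(kept, `[[`, integer(1), "align_len"))
  100 * num / den
}

## metric accessor shared by histogram/interval selection
hit_metric_values <- function(result, metric, labels = NULL) {
  hits <- result$hits
  if (!is.null(labels)) hits <- hits[match(labels, hit_ids(result))]
  v <- switch(metric,
    bit_score = vapply(hits, `[[`, numeric(1), "bit_score"),
    e_value = vapply(hits, `[[`, numeric(1), "e_value"),
    percent_similarity = vapply(hits, percent_similarity_of_hit, numeric(1),
                                program = result$program),
    coverage = vapply(hits, coverage_of_hit, numeric(1),
                      query_len = result$query_len,
                      program = result$program),
    stop_blastree("unknown metric: ", metric))
  names(v) <- vapply(hits, `[[`, character(1), "hit_id")
  v
}

#' Select hits by E-value threshold
#'
#' @param result a `blast_result`.
#' @param threshold inclusive upper bound on the hit's best E-value
#'   (>= 0; `Inf` selects everything).
#' @return character vector of hit labels.
#' @export
apply_evalue_threshold <- function(result, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop_blastree("threshold must be a single non-negative number")
  v <- hit_metric_values(result, "e_value")
  names(v)[v <= threshold]
}

#' Metric distribution of the hits
#'
#' Values ranked in decreasing order (the score-histogram view) plus
#' equal-width binning over `[min, max]` (the distribution view).  An empty
#' scope yields an empty histogram, not an error.
#'
#' @param result a `blast_result`.
#' @param metric one of `"bit_score"`, `"percent_similarity"`,
#'   `"coverage"`.
#' @param n_bins number of equal-width bins (default 20).
#' @param labels optional label subset defining the scope.
#' @return an object of class `metric_histogram`: `metric`, `values`
#'   (named, sorted decreasing), `breaks`, `counts`.
#' @export
metric_histogram <- function(result, metric, n_bins = 20L, labels = NULL) {
  v <- hit_metric_values(result, metric, labels)
  if (length(v) == 0L)
    return(structure(list(metric = metric, values = v,
                          breaks = numeric(0), counts = integer(0)),
                     class = "metric_histogram"))
  rng <- range(v)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  structure(list(metric = metric, values = sort(v, decreasing = TRUE),
                 breaks = breaks, counts = counts),
            class = "metric_histogram")
}

#' @export
print.metric_histogram <- function(x, ...) {
  cat(sprintf("<metric_histogram> %s: %d hit(s) in %d bin(s)\n",
              x$metric, length(x$values), length(x$counts)))
  invisible(x)
}

#' Write a metric histogram as TSV
#' @param hist a `metric_histogram`.
#' @param path output path.
#' @export
write_histogram_tsv <- function(hist, path) {
  tab <- data.frame(bin_low = utils::head(hist$breaks, -1L),
                    bin_high = hist$breaks[-1L], count = hist$counts)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select hits inside a closed metric interval
#'
#' Hits with `low <= metric <= high`.  A score-threshold "click" is
#' `select_interval(result, "bit_score", t, Inf)`.
#'
#' @param result a `blast_result`.
#' @param metric metric name (see [metric_histogram()]).
#' @param low,high closed interval bounds, `low <= high`.
#' @param labels optional label subset defining the scope.
#' @return character vector of hit labels.
#' @export
select_interval <- function(result, metric, low, high, labels = NULL) {
  if (low > high) stop_blastree("interval bounds out of order: low > high")
  v <- hit_metric_values(result, metric, labels)
  names(v)[v >= low & v <= high]
}

#' Top-N scoring hits
#'
#' The `n` highest-bit-score hits among those passing the active filters;
#' the remaining hits stay available to the large-scale tools.
#'
#' @param result a `blast_result` (hits are bit-score sorted).
#' @param n number of hits to keep (default 100); `n` larger than the
#'   available hits returns all of them.
#' @param within optional label set to restrict to (the active filter
#'   result).
#' @return character vector of hit labels, descending score order.
#' @export
top_n_hits <- function(result, n = 100L, within = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_blastree("n must be a single number >= 1")
  ids <- hit_ids(result)
  if (!is.null(within)) ids <- ids[ids %in% within]
  utils::head(ids, n)
}

#' Selection state
#'
#' A reproducible description of the active filters: E-value threshold,
#' closed metric intervals, taxon selections and the top-N view size.
#'
#' @param e_value inclusive E-value threshold (default `Inf`).
#' @param intervals list of `list(metric=, low=, high=)`.
#' @param taxa list of `list(taxon=, include=)`.
#' @param top_n top-N view size (default 100).
#' @param site_mode tree site mode carried along for reproducibility.
#' @return an object of class `selection_state`.
#' @export
selection_state <- function(e_value = Inf, intervals = list(),
                            taxa = list(), top_n = 100L,
                            site_mode = "all_sites") {
  if (top_n < 1L) stop_blastree("top_n must be >= 1")
  structure(list(e_value = e_value, intervals = intervals, taxa = taxa,
                 top_n = as.integer(top_n), site_mode = site_mode),
            class = "selection_state")
}

#' Apply a selection state
#'
#' Evaluates every active filter and intersects the label sets (pure
#' intersection semantics, so order is irrelevant).  The top-N view is NOT
#' applied here; pass the returned set to [top_n_hits()].
#'
#' @param result an annotated `blast_result`.
#' @param state a [selection_state()].
#' @param taxonomy a `taxonomy_table`, required when `state$taxa` is
#'   non-empty.
#' @return character vector of hit labels passing all filters.
#' @export
apply_selection <- function(result, state, taxonomy = NULL) {
  sel <- hit_ids(result)
  if (is.finite(state$e_value))
    sel <- intersect(sel, apply_evalue_threshold(result, state$e_value))
  for (iv in state$intervals)
    sel <- intersect(sel,
                     select_interval(result, iv$metric, iv$low, iv$high))
  if (length(state$taxa)) {
    if (is.null(taxonomy))
      stop_blastree("taxon filters require a taxonomy table")
    for (tx in state$taxa)
      sel <- intersect(sel, select_by_taxon(result, taxonomy, tx$taxon,
                                            include = isTRUE(tx$include)))
  }
  sel
}

#' Write a selection state to a plain-text config
#'
#' Flat `key=value` lines; intervals serialize as `metric:low:high`, taxa
#' as `taxon:include|exclude`.  Round-trips losslessly through
#' [read_selection_config()].
#'
#' @param state a `selection_state`.
#' @param path output path.
#' @export
write_selection_config <- function(state, path) {
  lines <- c(
    paste0("e_value=", format(state$e_value, digits = 15)),
    paste0("top_n=", state$top_n),
    paste0("site_mode=", state$site_mode),
    vapply(state$intervals, function(iv)
      sprintf("interval=%s:%s:%s", iv$metric,
              format(iv$low, digits = 15), format(iv$high, digits = 15)),
      character(1)),
    vapply(state$taxa, function(tx)
      sprintf("taxon=%s:%s", tx$taxon,
              if (isTRUE(tx$include)) "include" else "exclude"),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a selection state from its config file
#' @param path path written by [write_selection_config()].
#' @return a `selection_state`.
#' @export
read_selection_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  key <- sub("=.*", "", lines)
  val <- sub("^[^=]*=", "", lines)
  intervals <- lapply(val[key == "interval"], function(x) {
    p <- strsplit(x, ":", fixed = TRUE)[[1L]]
    list(metric = p[1L], low = as.numeric(p[2L]), high = as.numeric(p[3L]))
  })
  taxa <- lapply(val[key == "taxon"], function(x) {
    p <- strsplit(x, ":", fixed = TRUE)[[1L]]
    list(taxon = p[1L], include = identical(p[2L], "include"))
  })
  selection_state(
    e_value = as.numeric(val[key == "e_value"][1L]),
    intervals = intervals, taxa = taxa,
    top_n = as.integer(val[key == "top_n"][1L]),
    site_mode = val[key == "site_mode"][1L])
}
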