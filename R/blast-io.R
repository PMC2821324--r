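# Reading NCBI BLAST XML reports into the internal data model.
#
# The internal model mirrors the report structure: a blast_result holds an
# ordered list of blast_hit objects, each holding one or more HSPs (local
# gapped alignments).  Coordinates are 1-based inclusive throughout, the
# R/Bioconductor convention; minus-strand nucleotide HSPs are normalized at
# parse time (subject coordinates swapped, strand recorded).

SUPPORTED_PROGRAMS <- c("blastn", "blastp", "blastx", "tblastn")
MAX_HITS_DEFAULT <- 5000L

#' Construct a single high-scoring pair (HSP)
#'
#' An HSP is one local gapped alignment between the query and a database
#' subject, as reported by BLAST.  Coordinates are 1-based inclusive; for
#' BLASTX the query coordinates are nucleotide positions on the query while
#' the aligned strings are amino acids.
#'
#' @param query_start,query_end 1-based inclusive query coordinates.
#' @param hit_start,hit_end 1-based inclusive subject coordinates
#'   (normalized so that `hit_start <= hit_end`).
#' @param aligned_query,aligned_hit gapped alignment strings of equal length.
#' @param bit_score bit score of the HSP.
#' @param e_value expectation value (>= 0).
#' @param raw_score integer raw alignment score.
#' @param identities,positives counts of identical / positively scoring
#'   columns.
#' @param align_len number of alignment columns.
#' @param query_frame,hit_frame reading frames (0 for protein programs).
#' @param strand +1 or -1; -1 records a minus-strand subject.
#' @return an object of class `blast_hsp`.
#' @export
new_hsp <- function(query_start, query_end, hit_start, hit_end,
                    aligned_query, aligned_hit,
                    bit_score, e_value, raw_score = NA_integer_,
                    identities = NA_integer_, positives = NA_integer_,
                    align_len = nchar(aligned_query),
                    query_frame = 0L, hit_frame = 0L, strand = 1L) {
  structure(list(
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    hit_start = as.integer(hit_start), hit_end = as.integer(hit_end),
    aligned_query = toupper(aligned_query), aligned_hit = toupper(aligned_hit),
    bit_score = as.numeric(bit_score), raw_score = as.integer(raw_score),
    e_value = as.numeric(e_value),
    identities = as.integer(identities), positives = as.integer(positives),
    align_len = as.integer(align_len),
    query_frame = as.integer(query_frame), hit_frame = as.integer(hit_frame),
    strand = as.integer(strand)
  ), class = "blast_hsp")
}

## number of query residues (protein-level for blastx) spanned by an HSP
hsp_query_span <- function(hsp, program) {
  span <- hsp$query_end - hsp$query_start + 1L
  if (identical(program, "blastx")) span %/% 3L else span
}

validate_hsp <- function(hsp, program = "blastp", context = "") {
  fail <- function(msg) stop_blastree("invalid HSP", context, ": ", msg)
  if (nchar(hsp$aligned_query) != nchar(hsp$aligned_hit))
    fail("aligned strings differ in length")
  if (nchar(hsp$aligned_query) != hsp$align_len)
    fail("align_len does not match alignment strings")
  nres <- nchar(ungap(hsp$aligned_query))
  if (nres != hsp_query_span(hsp, program))
    fail(sprintf("query span %d-%d inconsistent with %d aligned residues",
                 hsp$query_start, hsp$query_end, nres))
  if (is.na(hsp$e_value) || hsp$e_value < 0) fail("negative E-value")
  if (!is.na(hsp$identities) && !is.na(hsp$positives) &&
      (hsp$identities > hsp$positives || hsp$positives > hsp$align_len))
    fail("identities/positives exceed alignment length")
  invisible(hsp)
}

#' Construct a BLAST hit (one database match)
#'
#' @param hit_id database identifier (used as the hit's label throughout the
#'   package; must be unique within a report).
#' @param accession accession string.
#' @param description free-text definition line.
#' @param hit_len subject length in residues.
#' @param hsps non-empty list of [new_hsp()] objects.
#' @param species,taxid,lineage optional taxonomy annotation (see
#'   [annotate_hits()]).
#' @return an object of class `blast_hit`.  The hit-level `bit_score` and
#'   `e_value` are those of its best (maximum bit score) HSP.
#' @export
new_blast_hit <- function(hit_id, accession = hit_id, description = "",
                          hit_len = NA_integer_, hsps,
                          species = NA_character_, taxid = NA_integer_,
                          lineage = NULL) {
  if (length(hsps) == 0L) stop_blastree("hit ", hit_id, " has no HSPs")
  bits <- vapply(hsps, `[[`, numeric(1), "bit_score")
  best <- which.max(bits)
  structure(list(
    hit_id = hit_id, accession = accession, description = description,
    hit_len = as.integer(hit_len), hsps = hsps,
    bit_score = bits[[best]], e_value = hsps[[best]]$e_value,
    species = species, taxid = as.integer(taxid), lineage = lineage
  ), class = "blast_hit")
}

#' Construct a parsed BLAST result
#'
#' Hits are sorted by descending best bit score (stable) and the global hit
#' cap is applied.
#'
#' @param program one of `"blastn"`, `"blastp"`, `"blastx"`, `"tblastn"`.
#'   TBLASTX reports are rejected: their overlapping reading-frame
#'   alignments cannot be post-processed at a single sequence level.
#' @param query_id,query_def query identifier and definition line.
#' @param query_seq ungapped query residue string (may be `NA` when absent
#'   from the report and no FASTA override is given).
#' @param query_len query length in residues (nucleotides for blastx).
#' @param db_name database name.
#' @param hits list of [new_blast_hit()] objects.
#' @param max_hits hit cap (default 5000).
#' @return an object of class `blast_result`.
#' @export
new_blast_result <- function(program, query_id, query_def = query_id,
                             query_seq = NA_character_, query_len,
                             db_name = "", hits = list(),
                             max_hits = MAX_HITS_DEFAULT) {
  program <- tolower(program)
  if (identical(program, "tblastx"))
    stop_blastree("unsupported program 'tblastx': ",
                  "overlapping reading-frame output cannot be post-processed")
  if (!program %in% SUPPORTED_PROGRAMS)
    stop_blastree("unknown BLAST program: ", program)
  if (length(hits)) {
    bits <- vapply(hits, `[[`, numeric(1), "bit_score")
    hits <- hits[order(-bits)]
    ids <- vapply(hits, `[[`, character(1), "hit_id")
    if (anyDuplicated(ids))
      stop_blastree("duplicate hit identifiers in report: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- structure(list(
    program = program, query_id = query_id, query_def = query_def,
    query_seq = if (is.na(query_seq)) NA_character_ else toupper(ungap(query_seq)),
    query_len = as.integer(query_len), db_name = db_name, hits = hits
  ), class = "blast_result")
  cap_hits(res, max_hits)
}

hit_ids <- function(result) vapply(result$hits, `[[`, character(1), "hit_id")

get_hit <- function(result, label) {
  i <- match(label, hit_ids(result))
  if (is.na(i)) stop_blastree("unknown hit label: ", label)
  result$hits[[i]]
}

#' Parse an NCBI BLAST XML report (outfmt 5)
#'
#' Reads a single-query report into a [new_blast_result()] object.  Only the
#' XML dialect is supported because HSP stacking requires the gapped
#' alignment strings, which tabular formats do not carry.
#'
#' @param path path to the BLAST XML file.
#' @param query_fasta optional FASTA file carrying the query sequence; used
#'   when the report itself does not embed it (the usual case).
#' @param max_hits hit cap applied after parsing (default 5000).
#' @return a `blast_result` with hits ordered by descending best bit score.
#' @export
parse_blast_xml <- function(path, query_fasta = NULL,
                            max_hits = MAX_HITS_DEFAULT) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_blastree(
                    "malformed BLAST XML in '", path, "': ", conditionMessage(e)))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "BlastOutput")
    stop_blastree("malformed BLAST XML: root element is <",
                  xml2::xml_name(root), ">, expected <BlastOutput>")
  txt1 <- function(node, xp) xml2::xml_text(xml2::xml_find_first(node, xp))
  program <- tolower(txt1(root, "./BlastOutput_program"))
  if (identical(program, "tblastx"))
    stop_blastree("unsupported program 'tblastx': ",
                  "overlapping reading-frame output cannot be post-processed")
  iters <- xml2::xml_find_all(root, ".//Iteration")
  if (length(iters) > 1L)
    stop_blastree("multi-query report (", length(iters),
                  " iterations); run one query per report")
  if (length(iters) == 0L)
    stop_blastree("malformed BLAST XML: no <Iteration> element")

  query_id <- txt1(root, "./BlastOutput_query-ID")
  query_def <- txt1(root, "./BlastOutput_query-def")
  query_len <- as.integer(txt1(root, "./BlastOutput_query-len"))
  db_name <- txt1(root, "./BlastOutput_db")
  query_seq <- txt1(root, ".//Iteration_query-seq")  # non-standard, optional
  if (is.na(query_seq)) query_seq <- NA_character_

  if (!is.null(query_fasta)) {
    qs <- Biostrings::readBStringSet(query_fasta)
    if (length(qs) == 0L) stop_blastree("empty query FASTA: ", query_fasta)
    query_seq <- as.character(qs[[1L]])
  }

  hit_nodes <- xml2::xml_find_all(iters[[1L]], ".//Hit")
  hits <- vector("list", length(hit_nodes))
  if (length(hit_nodes)) {
    ## vectorized field extraction over the hit nodeset
    f <- function(xp) xml2::xml_text(xml2::xml_find_first(hit_nodes, xp))
    h_id <- f("./Hit_id"); h_def <- f("./Hit_def")
    h_acc <- f("./Hit_accession"); h_len <- as.integer(f("./Hit_len"))
    n_hsp <- xml2::xml_length(xml2::xml_find_first(hit_nodes, "./Hit_hsps"))

    hsp_nodes <- xml2::xml_find_all(iters[[1L]], ".//Hsp")
    g <- function(xp) xml2::xml_text(xml2::xml_find_first(hsp_nodes, xp))
    gi <- function(xp) as.integer(g(xp))
    gn <- function(xp) as.numeric(g(xp))
    qs <- gi("./Hsp_query-from"); qe <- gi("./Hsp_query-to")
    hs <- gi("./Hsp_hit-from");   he <- gi("./Hsp_hit-to")
    bit <- gn("./Hsp_bit-score"); raw <- gi("./Hsp_score")
    ev <- gn("./Hsp_evalue")
    idn <- gi("./Hsp_identity"); pos <- gi("./Hsp_positive")
    alen <- gi("./Hsp_align-len")
    qf <- gi("./Hsp_query-frame"); hf <- gi("./Hsp_hit-frame")
    aq <- g("./Hsp_qseq"); ah <- g("./Hsp_hseq")
    qf[is.na(qf)] <- 0L; hf[is.na(hf)] <- 0L

    strand <- rep(1L, length(qs))
    minus <- !is.na(hs) & !is.na(he) & hs > he
    if (any(minus)) {  # minus-strand subject: swap coordinates, keep strings
      tmp <- hs[minus]; hs[minus] <- he[minus]; he[minus] <- tmp
      strand[minus] <- -1L
    }
    strand[hf < 0L] <- -1L

    idx <- rep(seq_along(hit_nodes), n_hsp)
    if (length(idx) != length(qs))
      stop_blastree("malformed BLAST XML: <Hit_hsps> children are not all <Hsp>")
    for (i in seq_along(hit_nodes)) {
      ks <- which(idx == i)
      hsps <- lapply(ks, function(k) {
        hsp <- new_hsp(qs[k], qe[k], hs[k], he[k], aq[k], ah[k],
                       bit_score = bit[k], e_value = ev[k], raw_score = raw[k],
                       identities = idn[k], positives = pos[k],
                       align_len = alen[k], query_frame = qf[k],
                       hit_frame = hf[k], strand = strand[k])
        validate_hsp(hsp, program, context = paste0(" in hit ", h_id[i]))
      })
      hits[[i]] <- new_blast_hit(h_id[i], accession = h_acc[i],
                                 description = h_def[i], hit_len = h_len[i],
                                 hsps = hsps)
    }
  }
  new_blast_result(program, query_id, query_def, query_seq, query_len,
                   db_name, hits, max_hits = max_hits)
}

#' Apply the global hit cap
#'
#' Keeps the first `min(n, max_hits)` hits of a score-sorted result, the
#' behaviour of a capped BLAST search (default cap 5,000 hits).
#'
#' @param result a `blast_result`.
#' @param max_hits maximum number of hits to retain (>= 1).
#' @return the capped `blast_result`; order preserved.
#' @export
cap_hits <- function(result, max_hits = MAX_HITS_DEFAULT) {
  if (!is.numeric(max_hits) || length(max_hits) != 1L || max_hits < 1)
    stop_blastree("max_hits must be a single number >= 1")
  if (length(result$hits) > max_hits)
    result$hits <- result$hits[seq_len(max_hits)]
  result
}

#' Per-hit feature table
#'
#' One row per hit with the metrics used throughout hit selection: best
#' E-value, best bit score, pooled percent similarity and query coverage.
#' Hits without taxonomy annotation get species `"unknown"`.
#'
#' @param result a `blast_result`.
#' @return a `data.frame` with columns `hit_id`, `species`, `e_value`,
#'   `bit_score`, `percent_similarity`, `coverage`.
#' @export
hit_feature_table <- function(result) {
  hits <- result$hits
  data.frame(
    hit_id = vapply(hits, `[[`, character(1), "hit_id"),
    species = vapply(hits, function(h)
      if (is.na(h$species)) "unknown" else h$species, character(1)),
    e_value = vapply(hits, `[[`, numeric(1), "e_value"),
    bit_score = vapply(hits, `[[`, numeric(1), "bit_score"),
    percent_similarity = vapply(hits, percent_similarity_of_hit, numeric(1),
                                program = result$program),
    coverage = vapply(hits, coverage_of_hit, numeric(1),
                      query_len = result$query_len, program = result$program),
    stringsAsFactors = FALSE
  )
}

#' Write a feature table as TSV
#'
#' @param table data.frame from [hit_feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.blast_result <- function(x, ...) {
  cat(sprintf("<blast_result> %s: query '%s' (%d residues) vs %s\n",
              x$program, x$query_def, x$query_len, x$db_name))
  cat(sprintf("  %d hits", length(x$hits)))
  if (length(x$hits))
    cat(sprintf("; best bit score %.1f (%s)",
                x$hits[[1]]$bit_score, x$hits[[1]]$hit_id))
  cat("\n")
  invisible(x)
}

#' @export
print.blast_hit <- function(x, ...) {
  cat(sprintf("<blast_hit> %s (%s): %d HSP(s), best %.1f bits, E=%.3g\n",
              x$hit_id, x$accession, length(x$hsps), x$bit_score, x$e_value))
  invisible(x)
}
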