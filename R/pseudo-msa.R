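# Query-anchored pseudo multiple alignment ("HSP stacking"): every hit
# residue is placed in the column of its homologous query residue, so the
# alignment is exactly as wide as the query.  Insertions in a hit relative
# to the query have no column and are dropped (a documented, lossy choice);
# regions of a hit outside its kept HSPs are gaps.

GAP <- "-"

#' Resolve a hit's HSPs for stacking
#'
#' Multiple non-overlapping HSPs of one hit are concatenated; when several
#' HSPs overlap on the query (duplicated domains: each repeat unit aligns to
#' the same query region), only the highest-scoring pair is kept.  Selection
#' is greedy by descending bit score (ties: lower query start, then input
#' order); an HSP overlapping any already-kept HSP on the query is discarded
#' entirely.  Adjacent intervals do not overlap.
#'
#' @param hit a `blast_hit`.
#' @param program BLAST program of the report (frame handling for blastx:
#'   only HSPs in the frame of the hit's best HSP are considered).
#' @return list of kept `blast_hsp` objects, in keep order.
#' @export
resolve_hsps <- function(hit, program = "blastp") {
  hsps <- hit$hsps
  if (identical(program, "blastx")) {
    frames <- vapply(hsps, `[[`, integer(1), "query_frame")
    best <- which.max(vapply(hsps, `[[`, numeric(1), "bit_score"))
    hsps <- hsps[frames == frames[best]]
  }
  bits <- vapply(hsps, `[[`, numeric(1), "bit_score")
  qs <- vapply(hsps, `[[`, integer(1), "query_start")
  ord <- order(-bits, qs, seq_along(hsps))
  kept <- list()
  for (k in ord) {
    cand <- hsps[[k]]
    clash <- any(vapply(kept, function(h)
      intervals_overlap(h$query_start, h$query_end,
                        cand$query_start, cand$query_end), logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- cand
  }
  kept
}

## protein-level query columns of an HSP (identity except for blastx, where
## nucleotide coordinates are mapped into codons of the HSP's frame)
hsp_query_columns <- function(hsp, program, query_len) {
  if (!identical(program, "blastx"))
    return(c(hsp$query_start, hsp$query_end))
  f <- hsp$query_frame
  if (f >= 1L) {
    p1 <- (hsp$query_start - f) %/% 3L + 1L
  } else {
    p1 <- (query_len - hsp$query_end + 1L - abs(f)) %/% 3L + 1L
  }
  c(p1, p1 + hsp_query_span(hsp, program) - 1L)
}

#' Build the query-anchored pseudo multiple alignment
#'
#' Stacks each hit's kept HSPs (see [resolve_hsps()]) onto query
#' coordinates.  Alignment columns where the query has a gap (insertions in
#' the hit) are dropped; query regions outside all kept HSPs are gap
#' characters.  The query itself is the first row and contains no gaps.
#'
#' For blastx reports the column space is the translated query in the frame
#' of the globally best HSP; hits whose best HSP is in another frame cannot
#' be projected onto those columns and are dropped with a warning.
#'
#' @param result a `blast_result` with a non-`NA` `query_seq` (for blastx,
#'   where the report carries the nucleotide query, the protein query row is
#'   reconstructed from the stacked HSPs; uncovered columns are `X`).
#' @param labels optional subset of hit labels to stack (default all).
#' @return an object of class `pseudo_msa`: `column_count`, `query_label`,
#'   `query_row`, named character vector `rows`.
#' @export
stack_hsps <- function(result, labels = NULL) {
  program <- result$program
  hits <- result$hits
  if (!is.null(labels)) {
    ids <- hit_ids(result)
    miss <- setdiff(labels, ids)
    if (length(miss)) stop_blastree("unknown hit label(s): ",
                                    paste(miss, collapse = ", "))
    hits <- hits[match(labels, ids)]
  }

  if (identical(program, "blastx")) {
    all_hsps <- unlist(lapply(hits, `[[`, "hsps"), recursive = FALSE)
    if (!length(all_hsps)) stop_blastree("no HSPs to stack")
    gbits <- vapply(all_hsps, `[[`, numeric(1), "bit_score")
    gframe <- all_hsps[[which.max(gbits)]]$query_frame
    W <- (result$query_len - abs(gframe) + 1L) %/% 3L
    in_frame <- vapply(hits, function(h) {
      fb <- which.max(vapply(h$hsps, `[[`, numeric(1), "bit_score"))
      h$hsps[[fb]]$query_frame == gframe
    }, logical(1))
    if (any(!in_frame))
      warning(sum(!in_frame), " hit(s) dropped: best HSP not in the query ",
              "frame (", gframe, ") of the top-scoring HSP", call. = FALSE)
    hits <- hits[in_frame]
    query_chars <- rep("X", W)
  } else {
    if (is.na(result$query_seq))
      stop_blastree("query sequence unavailable; supply it via the ",
                    "query_fasta argument of parse_blast_xml()")
    query_chars <- chars(result$query_seq)
    W <- result$query_len
    if (length(query_chars) != W)
      stop_blastree("query sequence length (", length(query_chars),
                    ") does not match reported query length (", W, ")")
  }

  rows <- vapply(hits, function(h) {
    row <- rep(GAP, W)
    for (hsp in resolve_hsps(h, program)) {
      aq <- chars(hsp$aligned_query)
      ah <- chars(hsp$aligned_hit)
      qcols <- hsp_query_columns(hsp, program, result$query_len)
      res_idx <- which(aq != GAP)
      if (length(res_idx) != qcols[2L] - qcols[1L] + 1L ||
          qcols[2L] > W || qcols[1L] < 1L)
        stop_blastree("HSP alignment of hit ", h$hit_id,
                      " violates query coordinate invariants")
      cols <- qcols[1L] + seq_along(res_idx) - 1L
      row[cols] <- ah[res_idx]
      if (identical(program, "blastx"))
        query_chars[cols] <<- aq[res_idx]
    }
    paste(row, collapse = "")
  }, character(1))
  names(rows) <- vapply(hits, `[[`, character(1), "hit_id")

  structure(list(
    column_count = W,
    query_label = result$query_id,
    query_row = paste(query_chars, collapse = ""),
    rows = rows,
    program = program,
    alphabet = if (identical(program, "blastn")) "nucleotide" else "protein"
  ), class = "pseudo_msa")
}

#' @export
print.pseudo_msa <- function(x, ...) {
  cat(sprintf("<pseudo_msa> %d columns, query '%s' + %d hit row(s)\n",
              x$column_count, x$query_label, length(x$rows)))
  invisible(x)
}

## rows (incl. query first) as a character matrix, one column per site
msa_char_matrix <- function(msa, labels = NULL) {
  all_labels <- c(msa$query_label, names(msa$rows))
  if (is.null(labels)) labels <- all_labels
  miss <- setdiff(labels, all_labels)
  if (length(miss))
    stop_blastree("unknown row label(s): ", paste(miss, collapse = ", "))
  seqs <- c(stats::setNames(msa$query_row, msa$query_label), msa$rows)[labels]
  do.call(rbind, lapply(seqs, chars))
}

#' Count gap-free sites for a selection
#'
#' Number of alignment columns with no gap in the query row nor in any
#' selected hit row — the usable-signal counter that is recomputed whenever
#' the selection changes.  With an empty selection this is the number of
#' columns, since the query row has no gaps.
#'
#' @param msa a `pseudo_msa`.
#' @param labels character vector of selected hit labels (may be empty).
#' @return integer count.
#' @export
gap_free_site_count <- function(msa, labels = character(0)) {
  if (length(labels) == 0L) return(msa$column_count)
  m <- msa_char_matrix(msa, unique(c(msa$query_label, labels)))
  sum(colSums(m == GAP) == 0L)
}

#' Insert external sequences into the pseudo alignment
#'
#' Each user-supplied sequence (at most five) is globally aligned to the
#' ungapped query (Needleman-Wunsch with affine gaps; BLOSUM62 for protein,
#' +2/-3 with gap open 5 / extend 2 for nucleotide) and then projected into
#' query columns exactly as HSP stacking does: insertions relative to the
#' query are dropped.  Rebuild the tree afterwards to place the external
#' sequences.
#'
#' @param msa a `pseudo_msa`.
#' @param seqs named character vector, `Biostrings::XStringSet`, or path to
#'   a FASTA file; 1 to 5 records.
#' @param alphabet `"protein"` or `"nucleotide"`; must match the alignment.
#' @param substitution_matrix optional scoring matrix overriding the
#'   default.
#' @param gap_opening,gap_extension affine gap costs (positive penalties).
#' @return the `pseudo_msa` with the external rows appended.
#' @export
insert_external_sequences <- function(msa, seqs,
                                      alphabet = c("protein", "nucleotide"),
                                      substitution_matrix = NULL,
                                      gap_opening = 5, gap_extension = 2) {
  alphabet <- match.arg(alphabet)
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs) &&
      is.null(names(seqs)))
    seqs <- Biostrings::readBStringSet(seqs)
  if (inherits(seqs, "XStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (!is.character(seqs) || is.null(names(seqs)) || any(names(seqs) == ""))
    stop_blastree("external sequences must be a named character vector or ",
                  "FASTA file")
  if (length(seqs) < 1L) stop_blastree("no external sequences supplied")
  if (length(seqs) > 5L)
    stop_blastree("at most five external sequences can be added (",
                  length(seqs), " supplied)")
  if (!identical(alphabet, msa$alphabet))
    stop_blastree("alphabet mismatch: alignment is ", msa$alphabet,
                  ", sequences declared ", alphabet)
  seqs <- toupper(gsub("[ \r\n-]", "", seqs))
  bad <- if (alphabet == "protein")
    grepl("[^ACDEFGHIKLMNPQRSTVWYXBZJUO*]", seqs)
  else grepl("[^ACGTUNRYSWKMBDHV]", seqs)
  if (any(bad))
    stop_blastree("sequence(s) not in the ", alphabet, " alphabet: ",
                  paste(names(seqs)[bad], collapse = ", "))

  if (is.null(substitution_matrix)) {
    substitution_matrix <- if (alphabet == "protein") "BLOSUM62"
    else Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  }
  query <- msa$query_row  # ungapped by construction

  new_rows <- vapply(seqs, function(s) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = s, subject = query, type = "global",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_opening, gapExtension = gap_extension)
    aq <- chars(as.character(Biostrings::alignedSubject(aln)))
    ah <- chars(as.character(Biostrings::alignedPattern(aln)))
    row <- rep(GAP, msa$column_count)
    row[aq != GAP] <- ah[aq != GAP]
    paste(row, collapse = "")
  }, character(1))
  names(new_rows) <- make.unique(c(names(msa$rows),
                                   sanitize_label(names(seqs))),
                                 sep = "_")[length(msa$rows) +
                                              seq_along(new_rows)]
  msa$rows <- c(msa$rows, new_rows)
  msa
}

#' Write the pseudo alignment as aligned FASTA
#'
#' @param msa a `pseudo_msa`.
#' @param path output path.
#' @param labels optional subset of hit labels (query always written first).
#' @export
write_pseudo_msa_fasta <- function(msa, path, labels = NULL) {
  if (is.null(labels)) labels <- names(msa$rows)
  seqs <- c(stats::setNames(msa$query_row, msa$query_label),
            msa$rows[labels])
  writeLines(unlist(lapply(names(seqs), function(l)
    c(paste0(">", l), seqs[[l]]))), path)
  invisible(path)
}

#' Per-row coverage intervals (BED-like)
#'
#' 0-based half-open intervals of non-gap runs per row, the data behind a
#' coverage/tiling diagram.
#'
#' @param msa a `pseudo_msa`.
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
coverage_intervals <- function(msa) {
  out <- lapply(names(msa$rows), function(l) {
    r <- rle(chars(msa$rows[[l]]) != GAP)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(label = l, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
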