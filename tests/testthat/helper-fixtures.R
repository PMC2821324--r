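# Hand-built truth objects (consumed by emit_blast_xml) and small
# convenience constructors for controlled fixtures.

## a truth-hit record with consistent coordinates, built from aligned strings
make_truth_hit <- function(hit_id, aligned_query, aligned_hit, query_start,
                           bit_score, e_value = 10^(-bit_score / 10),
                           accession = hit_id, species = "Escherichia coli",
                           taxid = 562L, description = NULL, extra_hsps = list()) {
  mk <- function(aq, ah, qs, bit, ev, h_start = 1L) {
    nres_q <- nchar(gsub("-", "", aq))
    nres_h <- nchar(gsub("-", "", ah))
    both <- strsplit(aq, "")[[1]] != "-" & strsplit(ah, "")[[1]] != "-"
    id <- sum(both & strsplit(aq, "")[[1]] == strsplit(ah, "")[[1]])
    new_hsp(qs, qs + nres_q - 1L, h_start, h_start + nres_h - 1L, aq, ah,
            bit_score = bit, e_value = ev, raw_score = round(2 * bit),
            identities = id, positives = id,
            align_len = nchar(aq))
  }
  hsps <- c(list(mk(aligned_query, aligned_hit, query_start, bit_score,
                    e_value)),
            lapply(extra_hsps, function(x)
              mk(x$aligned_query, x$aligned_hit, x$query_start, x$bit_score,
                 x$e_value %||% 10^(-x$bit_score / 10),
                 h_start = x$hit_start %||% 1L)))
  hit_len <- sum(vapply(hsps, function(p)
    nchar(gsub("-", "", p$aligned_hit)), integer(1)))
  list(hit_id = hit_id, accession = accession,
       description = description %||%
         sprintf("synthetic protein %s [%s]", hit_id, species),
       species = species, taxid = taxid,
       hit_seq = paste(vapply(hsps, function(p)
         gsub("-", "", p$aligned_hit), character(1)), collapse = ""),
       hit_len = hit_len, hsps = hsps, dup = FALSE, split = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_truth <- function(hits, query_seq, program = "blastp",
                       query_id = "QUERY") {
  structure(list(program = program, query_id = query_id,
                 query_def = paste(query_id, "test query"),
                 query_seq = query_seq, query_len = nchar(query_seq),
                 db_name = "test_db", hits = hits, tree = NULL, seed = 0L,
                 params = list()), class = "synthetic_truth")
}

## emit a truth to a temp file and parse it back
parse_truth <- function(truth, ...) {
  f <- tempfile(fileext = ".xml")
  on.exit(unlink(f))
  emit_blast_xml(truth, f)
  parse_blast_xml(f, ...)
}

## random protein string
rand_protein <- function(n) paste(sample(c("A","C","D","E","F","G","H","I",
  "K","L","M","N","P","Q","R","S","T","V","W","Y"), n, replace = TRUE),
  collapse = "")
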