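# Synthetic dataset generator: evolves hit sequences from a query along a
# known tree, engineers duplicated domains and multi-HSP splits, and emits
# the result as a BLAST XML report.  Ground truth (tree, per-hit HSP set,
# species assignments) is kept alongside so every downstream module can be
# tested against it without any network access.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

## substitute each residue independently with probability `rate`, drawing
## uniformly among the 19 other amino acids
evolve_seq <- function(seq, rate) {
  mut <- which(stats::runif(length(seq)) < rate)
  if (length(mut))
    seq[mut] <- vapply(seq[mut],
                       function(ch) sample(setdiff(AA_ALPHABET, ch), 1L), "")
  seq
}

#' Simulate a BLAST search result with known ground truth
#'
#' Evolves `n_hits` protein sequences from a random query along either a
#' star tree or a random bifurcating topology.  Substitutions are i.i.d.
#' uniform replacements (each site mutates with the per-edge probability and
#' is replaced by one of the 19 other residues), so on a star tree the
#' expected query-hit p-distance equals `sub_rate`.  On a random topology
#' every edge gets substitution probability `sub_rate` scaled by a
#' uniform(0.5, 1.5) edge-length factor.  Optional indels (geometric
#' lengths), engineered tandem duplications (two HSPs overlapping on the
#' same query interval, with distinct scores) and long-deletion HSP splits
#' exercise the stacking rules.  Scores are synthetic and monotone
#' decreasing in edit distance; E-values are `10^(-bit_score/10)`.
#'
#' @param n_hits number of hits (>= 1).
#' @param query_len query length in residues (default 300).
#' @param tree_shape `"random"` (bifurcating, query is one leaf) or
#'   `"star"` (each hit evolves independently from the query).
#' @param sub_rate per-edge substitution probability in `[0, 1]`.
#' @param indel_rate per-site indel probability in `[0, 1]` applied on each
#'   hit's terminal branch.
#' @param dup_fraction fraction of hits receiving a tandem domain
#'   duplication.
#' @param split_fraction fraction of hits whose alignment is split into two
#'   non-overlapping HSPs by a long deletion.
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @return an object of class `synthetic_truth` with the generating tree
#'   (`phylo`, tip labels `QUERY`/`HIT_...`; `NULL` for a star), the query
#'   sequence, and per-hit truth records (sequence, species, HSP set).
#' @export
simulate_dataset <- function(n_hits, query_len = 300L,
                             tree_shape = c("random", "star"),
                             sub_rate = 0.05, indel_rate = 0,
                             dup_fraction = 0, split_fraction = 0,
                             seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  for (r in c(sub_rate, indel_rate, dup_fraction, split_fraction))
    if (!is.numeric(r) || r < 0 || r > 1)
      stop_blastree("rates and fractions must lie in [0, 1]")
  if (n_hits < 1L) stop_blastree("n_hits must be >= 1")
  set.seed(as.integer(seed))

  hit_labels <- sprintf("HIT_%04d", seq_len(n_hits))
  if (tree_shape == "star") {
    query_seq <- sample(AA_ALPHABET, query_len, replace = TRUE)
    hit_seqs <- lapply(seq_len(n_hits), function(i)
      evolve_seq(query_seq, sub_rate))
    tree <- NULL
  } else {
    ntip <- n_hits + 1L
    tree <- ape::rtree(ntip, br = NULL)
    tree$tip.label <- c("QUERY", hit_labels)
    tree$edge.length <- stats::runif(nrow(tree$edge), 0.5, 1.5)
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- sample(AA_ALPHABET, query_len, replace = TRUE)
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(ord$edge)))
      seqs[[ord$edge[k, 2L]]] <-
        evolve_seq(seqs[[ord$edge[k, 1L]]], sub_rate * ord$edge.length[k])
    query_seq <- seqs[[1L]]
    hit_seqs <- seqs[1L + seq_len(n_hits)]
  }

  sp <- fixture_species()
  is_dup <- stats::runif(n_hits) < dup_fraction
  is_split <- !is_dup & stats::runif(n_hits) < split_fraction &
    query_len >= 60L

  hits <- vector("list", n_hits)
  for (i in seq_len(n_hits)) {
    spi <- sp[(i - 1L) %% nrow(sp) + 1L, ]
    hits[[i]] <- build_truth_hit(
      hit_id = hit_labels[i], accession = sprintf("SYN%05d", i),
      species = spi$name, taxid = spi$taxid,
      query_seq = query_seq, hit_seq = hit_seqs[[i]],
      indel_rate = indel_rate, dup = is_dup[i], split = is_split[i],
      sub_rate = sub_rate)
  }
  bits <- vapply(hits, function(h) max(vapply(h$hsps, `[[`, numeric(1),
                                              "bit_score")), numeric(1))
  hits <- hits[order(-bits)]

  structure(list(
    program = "blastp", query_id = "QUERY",
    query_def = "QUERY synthetic query protein",
    query_seq = paste(query_seq, collapse = ""), query_len = query_len,
    db_name = "synthetic_db", hits = hits, tree = tree,
    seed = as.integer(seed),
    params = list(n_hits = n_hits, query_len = query_len,
                  tree_shape = tree_shape, sub_rate = sub_rate,
                  indel_rate = indel_rate, dup_fraction = dup_fraction,
                  split_fraction = split_fraction)
  ), class = "synthetic_truth")
}

## synthetic score scheme: monotone decreasing in mismatches and gaps
score_hsp <- function(aq, ah) {
  both <- aq != "-" & ah != "-"
  id <- sum(both & aq == ah)
  mm <- sum(both & aq != ah)
  gp <- sum(!both)
  raw <- max(1L, 2L * id - mm - 2L * gp)
  list(identities = id, positives = id + stats::rbinom(1L, mm, 0.5),
       raw_score = raw, bit_score = raw / 2,
       e_value = 10^(-(raw / 2) / 10), align_len = length(aq))
}

## assemble one truth hit: base per-position alignment to the query plus
## optional indels, HSP split (long deletion) or tandem duplication
build_truth_hit <- function(hit_id, accession, species, taxid,
                            query_seq, hit_seq, indel_rate, dup, split,
                            sub_rate) {
  L <- length(query_seq)
  mk_hsp <- function(aq, ah, q_start, q_end, h_start, h_end) {
    sc <- score_hsp(aq, ah)
    new_hsp(q_start, q_end, h_start, h_end,
            paste(aq, collapse = ""), paste(ah, collapse = ""),
            bit_score = sc$bit_score, e_value = sc$e_value,
            raw_score = sc$raw_score, identities = sc$identities,
            positives = sc$positives, align_len = sc$align_len)
  }

  if (dup) {
    ## tandem duplication: two repeat units, each aligning to the same query
    ## segment; the second copy is more diverged, so its HSP scores lower
    seg_len <- max(20L, L %/% 3L)
    a <- sample.int(L - seg_len + 1L, 1L)
    b <- a + seg_len - 1L
    copy1 <- hit_seq[a:b]
    copy2 <- evolve_seq(hit_seq[a:b], min(0.9, sub_rate + 0.2))
    h1 <- mk_hsp(query_seq[a:b], copy1, a, b, 1L, seg_len)
    h2 <- mk_hsp(query_seq[a:b], copy2, a, b, seg_len + 1L, 2L * seg_len)
    if (h2$bit_score >= h1$bit_score) {  # enforce distinct, ordered scores
      h2$raw_score <- h1$raw_score - 1L
      h2$bit_score <- h2$raw_score / 2
      h2$e_value <- 10^(-h2$bit_score / 10)
    }
    full <- paste(c(copy1, copy2), collapse = "")
    return(list(hit_id = hit_id, accession = accession,
                description = sprintf("synthetic protein %s [%s]",
                                      hit_id, species),
                species = species, taxid = taxid,
                hit_seq = full, hit_len = nchar(full),
                hsps = list(h1, h2), dup = TRUE, split = FALSE))
  }

  residues <- hit_seq                      # aligned to query positions
  if (split) {
    g <- sample(8:15, 1L)
    s <- sample(seq(L %/% 3L, 2L * L %/% 3L - g), 1L)
    residues[s:(s + g - 1L)] <- "-"
  }
  if (indel_rate > 0) {
    del <- stats::runif(L) < indel_rate / 2
    residues[del] <- "-"
  }
  covered <- residues != "-"
  if (!any(covered)) { residues[1L] <- hit_seq[1L]; covered[1L] <- TRUE }

  ## insertions relative to the query, only at interior covered positions
  insertions <- vector("list", L)
  if (indel_rate > 0) {
    interior <- which(covered)
    interior <- interior[interior > min(which(covered)) &
                           interior < max(which(covered))]
    ins_at <- interior[stats::runif(length(interior)) < indel_rate / 2]
    for (p in ins_at)
      insertions[[p]] <- sample(AA_ALPHABET, stats::rgeom(1L, 0.5) + 1L,
                                replace = TRUE)
  }

  ## split the covered range into HSP segments at deletion runs >= 8
  qs <- min(which(covered)); qe <- max(which(covered))
  segs <- list(); cur_start <- qs; run <- 0L
  for (p in qs:qe) {
    if (covered[p]) {
      if (run >= 8L) { segs[[length(segs) + 1L]] <- c(cur_start, last_cov)
                       cur_start <- p }
      run <- 0L; last_cov <- p
    } else run <- run + 1L
  }
  segs[[length(segs) + 1L]] <- c(cur_start, qe)

  ## hit residue counter, walked in query order, gives subject coordinates
  hsps <- list(); h_pos <- 0L; full <- character(0)
  seg_i <- 1L
  for (p in qs:qe) {
    if (seg_i <= length(segs) && p == segs[[seg_i]][1L]) h_start <- h_pos + 1L
    if (covered[p]) { h_pos <- h_pos + 1L; full <- c(full, residues[p]) }
    closing <- seg_i <= length(segs) && p == segs[[seg_i]][2L]
    if (closing) {
      seg <- segs[[seg_i]]
      aq <- character(0); ah <- character(0)
      for (q in seg[1L]:seg[2L]) {
        aq <- c(aq, query_seq[q]); ah <- c(ah, residues[q])
        if (q < seg[2L] && length(insertions[[q]])) {
          aq <- c(aq, rep("-", length(insertions[[q]])))
          ah <- c(ah, insertions[[q]])
        }
      }
      hsps[[length(hsps) + 1L]] <-
        mk_hsp(aq, ah, seg[1L], seg[2L], h_start, h_pos)
      seg_i <- seg_i + 1L
    }
    if (length(insertions[[p]]) && (!closing || p < qe)) {
      ## insertions after a segment's last residue sit between HSPs
      h_pos <- h_pos + length(insertions[[p]])
      full <- c(full, insertions[[p]])
    }
  }
  full <- paste(full, collapse = "")
  list(hit_id = hit_id, accession = accession,
       description = sprintf("synthetic protein %s [%s]", hit_id, species),
       species = species, taxid = taxid,
       hit_seq = full, hit_len = nchar(full),
       hsps = hsps, dup = FALSE, split = split)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d hits, query %d aa, %s tree, seed %d\n",
              length(x$hits), x$query_len, x$params$tree_shape, x$seed))
  invisible(x)
}

#' Convert a synthetic truth to a parsed-report object
#'
#' Builds the `blast_result` that parsing the emitted XML should reproduce;
#' used to verify the emitter/parser round trip.
#'
#' @param truth a `synthetic_truth`.
#' @return a `blast_result`.
#' @export
as_blast_result <- function(truth) {
  hits <- lapply(truth$hits, function(h)
    new_blast_hit(h$hit_id, accession = h$accession,
                  description = h$description, hit_len = h$hit_len,
                  hsps = h$hsps))
  new_blast_result(truth$program, truth$query_id, truth$query_def,
                   truth$query_seq, truth$query_len, truth$db_name, hits,
                   max_hits = max(length(hits), MAX_HITS_DEFAULT))
}

#' Emit a synthetic truth as a BLAST XML report
#'
#' Writes a well-formed single-query report in the NCBI XML dialect
#' (outfmt 5) that [parse_blast_xml()] consumes.  The query sequence is
#' embedded as an `Iteration_query-seq` element so the fixture is
#' self-contained; a separate FASTA can be written with
#' [write_query_fasta()].
#'
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @param include_query_seq embed the query sequence (default `TRUE`).
#' @return `path`, invisibly.
#' @export
emit_blast_xml <- function(truth, path, include_query_seq = TRUE) {
  num <- function(x) as.character(x)
  hit_blocks <- vapply(seq_along(truth$hits), function(i) {
    h <- truth$hits[[i]]
    hsp_blocks <- vapply(seq_along(h$hsps), function(j) {
      p <- h$hsps[[j]]
      paste0(
        "      <Hsp>\n",
        "        <Hsp_num>", j, "</Hsp_num>\n",
        "        <Hsp_bit-score>", num(p$bit_score), "</Hsp_bit-score>\n",
        "        <Hsp_score>", p$raw_score, "</Hsp_score>\n",
        "        <Hsp_evalue>", num(p$e_value), "</Hsp_evalue>\n",
        "        <Hsp_query-from>", p$query_start, "</Hsp_query-from>\n",
        "        <Hsp_query-to>", p$query_end, "</Hsp_query-to>\n",
        "        <Hsp_hit-from>", p$hit_start, "</Hsp_hit-from>\n",
        "        <Hsp_hit-to>", p$hit_end, "</Hsp_hit-to>\n",
        "        <Hsp_query-frame>0</Hsp_query-frame>\n",
        "        <Hsp_hit-frame>0</Hsp_hit-frame>\n",
        "        <Hsp_identity>", p$identities, "</Hsp_identity>\n",
        "        <Hsp_positive>", p$positives, "</Hsp_positive>\n",
        "        <Hsp_align-len>", p$align_len, "</Hsp_align-len>\n",
        "        <Hsp_qseq>", p$aligned_query, "</Hsp_qseq>\n",
        "        <Hsp_hseq>", p$aligned_hit, "</Hsp_hseq>\n",
        "      </Hsp>\n")
    }, character(1))
    paste0(
      "    <Hit>\n",
      "      <Hit_num>", i, "</Hit_num>\n",
      "      <Hit_id>", xml_escape(h$hit_id), "</Hit_id>\n",
      "      <Hit_def>", xml_escape(h$description), "</Hit_def>\n",
      "      <Hit_accession>", xml_escape(h$accession), "</Hit_accession>\n",
      "      <Hit_len>", h$hit_len, "</Hit_len>\n",
      "      <Hit_hsps>\n", paste(hsp_blocks, collapse = ""),
      "      </Hit_hsps>\n",
      "    </Hit>\n")
  }, character(1))

  xml <- paste0(
    "<?xml version=\"1.0\"?>\n",
    "<!DOCTYPE BlastOutput PUBLIC \"-//NCBI//NCBI BlastOutput/EN\" ",
    "\"http://www.ncbi.nlm.nih.gov/dtd/NCBI_BlastOutput.dtd\">\n",
    "<BlastOutput>\n",
    "  <BlastOutput_program>", truth$program, "</BlastOutput_program>\n",
    "  <BlastOutput_version>blastree synthetic emitter</BlastOutput_version>\n",
    "  <BlastOutput_db>", xml_escape(truth$db_name), "</BlastOutput_db>\n",
    "  <BlastOutput_query-ID>", xml_escape(truth$query_id),
    "</BlastOutput_query-ID>\n",
    "  <BlastOutput_query-def>", xml_escape(truth$query_def),
    "</BlastOutput_query-def>\n",
    "  <BlastOutput_query-len>", truth$query_len, "</BlastOutput_query-len>\n",
    "  <BlastOutput_iterations>\n",
    "  <Iteration>\n",
    "    <Iteration_iter-num>1</Iteration_iter-num>\n",
    "    <Iteration_query-ID>", xml_escape(truth$query_id),
    "</Iteration_query-ID>\n",
    "    <Iteration_query-len>", truth$query_len, "</Iteration_query-len>\n",
    if (include_query_seq)
      paste0("    <Iteration_query-seq>", truth$query_seq,
             "</Iteration_query-seq>\n") else "",
    "    <Iteration_hits>\n",
    paste(hit_blocks, collapse = ""),
    "    </Iteration_hits>\n",
    "  </Iteration>\n",
    "  </BlastOutput_iterations>\n",
    "</BlastOutput>\n")
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Write the synthetic query as FASTA
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_query_fasta <- function(truth, path) {
  writeLines(c(paste0(">", truth$query_id, " ", truth$query_def),
               truth$query_seq), path)
  invisible(path)
}

#' Write the full synthetic hit sequences as FASTA
#'
#' Usable as the optional subject database for full-sequence FASTA export.
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_hit_fasta <- function(truth, path) {
  lines <- unlist(lapply(truth$hits, function(h)
    c(paste0(">", h$hit_id, " ", h$description), h$hit_seq)))
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-hit truth table as TSV
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  tab <- data.frame(
    hit_id = vapply(truth$hits, `[[`, character(1), "hit_id"),
    accession = vapply(truth$hits, `[[`, character(1), "accession"),
    species = vapply(truth$hits, `[[`, character(1), "species"),
    taxid = vapply(truth$hits, `[[`, integer(1), "taxid"),
    hit_len = vapply(truth$hits, `[[`, integer(1), "hit_len"),
    n_hsps = vapply(truth$hits, function(h) length(h$hsps), integer(1)),
    dup = vapply(truth$hits, `[[`, logical(1), "dup"),
    split = vapply(truth$hits, `[[`, logical(1), "split"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
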