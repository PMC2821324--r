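# Uncorrected p-distances over the pseudo alignment.  Two site modes:
# "all_sites" uses pairwise deletion (per pair, the columns where both rows
# have residues); "gap_free" restricts every pair to the columns with no gap
# in any selected row.

#' p-distance matrix over selected rows
#'
#' Proportion of differing sites among compared sites, uncorrected for
#' multiple substitutions.  A pair with zero comparable columns gets
#' distance 1 with a warning.
#'
#' @param msa a `pseudo_msa`.
#' @param labels row labels to compare (hit labels and/or the query label);
#'   default: query plus all hit rows.  At least two required.
#' @param site_mode `"all_sites"` (pairwise deletion) or `"gap_free"`
#'   (columns gap-free across all selected rows; errors when none exist).
#' @return symmetric matrix of class `p_distance_matrix` with a
#'   `site_mode` attribute.
#' @export
p_distance_matrix <- function(msa, labels = NULL,
                              site_mode = c("all_sites", "gap_free")) {
  site_mode <- match.arg(site_mode)
  if (is.null(labels)) labels <- c(msa$query_label, names(msa$rows))
  labels <- unique(labels)
  if (length(labels) < 2L)
    stop_blastree("need at least two rows to compute distances")
  m <- msa_char_matrix(msa, labels)
  if (site_mode == "gap_free") {
    ok <- colSums(m == GAP) == 0L
    if (!any(ok))
      stop_blastree("no gap-free columns for this selection; ",
                    "use site_mode = \"all_sites\"")
    m <- m[, ok, drop = FALSE]
  }
  k <- length(labels)
  d <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      comp <- m[i, ] != GAP & m[j, ] != GAP
      n <- sum(comp)
      if (n == 0L) {
        warning("rows '", labels[i], "' and '", labels[j],
                "' share no comparable columns; distance set to 1",
                call. = FALSE)
        d[i, j] <- d[j, i] <- 1
      } else {
        d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / n
      }
    }
  }
  structure(d, site_mode = site_mode, class = c("p_distance_matrix", "matrix"))
}
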