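# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## remove gap characters
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

## closed 1-based intervals [s1,e1], [s2,e2] overlap?  Adjacent intervals
## (e1 + 1 == s2) do not overlap, matching half-open semantics.
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

## total length of the union of closed integer intervals given as a
## two-column matrix (start, end); empty input -> 0
interval_union_length <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(0L)
  o <- order(iv[, 1L], iv[, 2L])
  iv <- iv[o, , drop = FALSE]
  total <- 0L
  cur_s <- iv[1L, 1L]; cur_e <- iv[1L, 2L]
  for (k in seq_len(nrow(iv))[-1L]) {
    s <- iv[k, 1L]; e <- iv[k, 2L]
    if (s <= cur_e + 1L) {
      cur_e <- max(cur_e, e)
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- s; cur_e <- e
    }
  }
  total + (cur_e - cur_s + 1L)
}

## Newick-safe label: spaces to underscores, structural characters stripped
sanitize_label <- function(x) {
  x <- gsub("[ \t]+", "_", x)
  gsub("[():,;'\"\\[\\]]", "", x, perl = TRUE)
}

stop_blastree <- function(...) stop(..., call. = FALSE)

## XML text escaping for the synthetic report emitter
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
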