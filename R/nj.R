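# Neighbor joining, implemented from the textbook recurrences (Saitou &
# Nei 1987; Studier & Keppler 1988).  Deterministic: ties in the Q-criterion
# are broken by the smallest (i, j) index pair in the current cluster order
# (new clusters are appended at the end).  Negative branch lengths are
# clamped to zero and the total deficit recorded.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative NJ: at each step the pair minimizing
#' `Q(i,j) = (m-2) d(i,j) - r_i - r_j` is joined, branch lengths follow the
#' usual rate-corrected split, and the reduced matrix uses
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`.  Exact on additive distances.
#' The result is unrooted (root node of degree three); with two leaves the
#' single distance is split in half.
#'
#' @param d symmetric numeric matrix with zero diagonal and non-negative
#'   entries (e.g. from [p_distance_matrix()]); row names are leaf labels.
#' @return an object of class `similarity_tree` wrapping an `ape::phylo`
#'   tree; the attribute `clamp_deficit` records the summed magnitude of
#'   negative branch lengths clamped to zero (0 on additive input).
#' @export
neighbor_joining <- function(d) {
  site_mode <- attr(d, "site_mode") %||% NA_character_
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_blastree("distance input must be a square matrix")
  if (any(d < 0)) stop_blastree("negative distances are not allowed")
  if (max(abs(d - t(d))) > 1e-8)
    stop_blastree("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stop_blastree("distance matrix diagonal must be zero")
  labs <- rownames(d) %||% paste0("L", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop_blastree("need at least two leaves")

  if (n == 2L) {
    phy <- structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
      edge.length = rep(d[1L, 2L] / 2, 2L),
      tip.label = labs, Nnode = 1L), class = "phylo")
    return(new_similarity_tree(phy, site_mode, clamp_deficit = 0))
  }

  reps <- seq_len(n)          # phylo node id of each active cluster
  next_internal <- n + 2L     # n + 1 reserved for the final (root) node
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  clamp_deficit <- 0
  add_edge <- function(p, c, l) {
    if (l < 0) { clamp_deficit <<- clamp_deficit - l; l <- 0 }
    parent <<- c(parent, p); child <<- c(child, c); elen <<- c(elen, l)
  }
  D <- d
  m <- n
  while (m > 3L) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    ## smallest (i, j), i < j, among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]

    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    u <- next_internal; next_internal <- next_internal + 1L
    add_edge(u, reps[i], bi)
    add_edge(u, reps[j], bj)

    others <- setdiff(seq_len(m), c(i, j))
    du <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], du),
               c(du, 0))
    reps <- c(reps[others], u)
    m <- m - 1L
  }
  ## resolve the final three clusters around the root with the three-point
  ## formulas
  root <- n + 1L
  l1 <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  l2 <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  l3 <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  add_edge(root, reps[1L], l1)
  add_edge(root, reps[2L], l2)
  add_edge(root, reps[3L], l3)

  phy <- structure(list(
    edge = cbind(parent, child, deparse.level = 0),
    edge.length = elen, tip.label = labs, Nnode = n - 2L),
    class = "phylo")
  phy <- renumber_preorder(phy)
  new_similarity_tree(phy, site_mode, clamp_deficit = clamp_deficit)
}

## renumber internal nodes in preorder from the root (ape convention:
## tips 1..n, root n+1) and order edge rows cladewise
renumber_preorder <- function(phy) {
  n <- length(phy$tip.label)
  root_old <- setdiff(phy$edge[, 1L], phy$edge[, 2L])[1L]
  map <- integer(max(phy$edge))
  map[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  new_edge <- matrix(0L, nrow(phy$edge), 2L)
  new_len <- numeric(nrow(phy$edge))
  row_i <- 0L
  visit <- function(node) {
    if (node > n) { map[node] <<- nxt; nxt <<- nxt + 1L }
    ks <- which(phy$edge[, 1L] == node)
    for (k in ks) {
      ch <- phy$edge[k, 2L]
      my_row <- row_i + 1L; row_i <<- my_row
      new_len[my_row] <<- phy$edge.length[k]
      new_edge[my_row, 1L] <<- map[node]
      if (ch <= n) {
        new_edge[my_row, 2L] <<- ch
      } else {
        visit(ch)
        new_edge[my_row, 2L] <<- map[ch]
      }
    }
  }
  visit(root_old)
  phy$edge <- new_edge
  phy$edge.length <- new_len
  phy
}
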