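# Independent oracles: a second, naive NJ implementation; exhaustive
# topology search with least-squares edge fitting; brute-force recomputation
# of alignment metrics.  These deliberately share no code with the package
# internals they check.

## --- naive textbook NJ, building a Newick string directly -----------------
naive_nj_newick <- function(D) {
  labs <- rownames(D)
  nwk <- labs
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  while (length(nwk) > 3L) {
    m <- nrow(D)
    r <- sapply(seq_len(m), function(i) sum(D[i, ]))
    best <- c(Inf, 0L, 0L)
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      q <- (m - 2) * D[i, j] - r[i] - r[j]
      if (q < best[1L]) best <- c(q, i, j)
    }
    i <- best[2L]; j <- best[3L]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(max(bi, 0)),
                      nwk[j], fmt(max(bj, 0)))
    keep <- setdiff(seq_len(m), c(i, j))
    du <- sapply(keep, function(k) (D[i, k] + D[j, k] - D[i, j]) / 2)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du), c(du, 0))
    nwk <- c(nwk[keep], merged)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(max(l1, 0)),
          nwk[2], fmt(max(l2, 0)), nwk[3], fmt(max(l3, 0)))
}

## --- exhaustive unrooted topologies via sequential leaf insertion ---------
## each topology: list(edges = 2-col matrix of node ids, n_leaves)
all_topologies <- function(n) {
  stopifnot(n >= 3, n <= 7)
  base <- list(list(edges = rbind(c(n + 1L, 1L), c(n + 1L, 2L),
                                  c(n + 1L, 3L)),
                    next_node = n + 2L))
  for (leaf in seq(4L, length.out = max(0L, n - 3L))) {
    out <- list()
    for (t in base) {
      for (e in seq_len(nrow(t$edges))) {
        new_int <- t$next_node
        edges <- t$edges[-e, , drop = FALSE]
        edges <- rbind(edges,
                       c(t$edges[e, 1L], new_int),
                       c(new_int, t$edges[e, 2L]),
                       c(new_int, leaf))
        out[[length(out) + 1L]] <- list(edges = edges,
                                        next_node = new_int + 1L)
      }
    }
    base <- out
  }
  base
}

## least-squares edge fit of a topology to a distance matrix; returns RSS
## and the fitted tree as newick
ls_fit_topology <- function(topo, D, labs) {
  n <- nrow(D)
  edges <- topo$edges
  nE <- nrow(edges)
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(nodes, function(v) which(edges[, 1L] == v | edges[, 2L] == v))
  names(adj) <- nodes
  path_edges <- function(a, b) {  # BFS over the tree
    prev <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
    prev_edge <- prev
    queue <- a; seen <- as.character(a)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v == b) break
      for (e in adj[[as.character(v)]]) {
        w <- if (edges[e, 1L] == v) edges[e, 2L] else edges[e, 1L]
        if (!as.character(w) %in% seen) {
          seen <- c(seen, as.character(w))
          prev[as.character(w)] <- v
          prev_edge[as.character(w)] <- e
          queue <- c(queue, w)
        }
      }
    }
    path <- integer(0); v <- b
    while (v != a) { path <- c(path, prev_edge[[as.character(v)]])
                     v <- prev[[as.character(v)]] }
    path
  }
  pairs <- t(utils::combn(n, 2L))
  P <- matrix(0, nrow(pairs), nE)
  y <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    P[k, path_edges(pairs[k, 1L], pairs[k, 2L])] <- 1
    y[k] <- D[pairs[k, 1L], pairs[k, 2L]]
  }
  fit <- stats::lm.fit(P, y)
  rss <- sum(fit$residuals^2)
  b <- fit$coefficients; b[is.na(b)] <- 0
  ## newick: root at the internal neighbour of leaf `n`
  to_nwk <- function(v, from_edge) {
    es <- setdiff(adj[[as.character(v)]], from_edge)
    if (!length(es)) return(labs[v])
    parts <- vapply(es, function(e) {
      w <- if (edges[e, 1L] == v) edges[e, 2L] else edges[e, 1L]
      paste0(to_nwk(w, e), ":", format(b[e], digits = 12))
    }, character(1))
    if (v <= n) labs[v] else paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- edges[adj[[as.character(1L)]][1L], ]
  root <- root[root != 1L]
  list(rss = rss, newick = paste0(to_nwk(root, NA_integer_), ";"))
}

## --- brute-force metric recomputation -------------------------------------
## gap-free column count by direct scan over string rows
naive_gap_free <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  sum(apply(m, 2L, function(col) all(col != "-")))
}

## p-distance by direct column scan
naive_p_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  comp <- a != "-" & b != "-"
  if (!sum(comp)) return(1)
  sum(a[comp] != b[comp]) / sum(comp)
}

## coverage by per-position marking over kept HSP intervals
naive_coverage <- function(kept, query_len) {
  pos <- logical(query_len)
  for (h in kept) pos[h$query_start:h$query_end] <- TRUE
  mean(pos)
}

## random additive distance matrix from a random tree; returns both
random_additive <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  D <- stats::cophenetic(tr)
  ord <- sample(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

rf_dist <- function(t1, t2) phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
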