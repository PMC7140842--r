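# Independent brute-force oracles. These deliberately share no code with the
# package: pure-R double loops, Floyd-Warshall, exhaustive path enumeration
# and direct hypergeometric summation.

# Erdos-Renyi edge table + ppi_network, with node names kept even if isolated.
rand_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- cbind(nodes[pairs[keep, 1L]], nodes[pairs[keep, 2L]])
  list(nodes = nodes, edges = edges,
       net = ppi_network(edges, nodes = nodes))
}

# Adjacency matrix from a node list + edge table.
adj_matrix <- function(nodes, edges) {
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (length(edges) && nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      A[edges[r, 1L], edges[r, 2L]] <- 1L
      A[edges[r, 2L], edges[r, 1L]] <- 1L
    }
  }
  A
}

# All-pairs shortest paths by Floyd-Warshall (triple loop).
oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n, dimnames = dimnames(A))
  d[A == 1L] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# IAD by explicit double loop over ordered pairs (Eq.-style sum).
oracle_iad <- function(d, genes) {
  n <- length(genes)
  tot <- 0
  for (i in genes) for (j in genes) if (i != j) tot <- tot + d[i, j]
  tot / (n * (n - 1))
}

# IED as the sum of the two directional means, each by explicit loops.
oracle_ied <- function(d, p, q) {
  dir1 <- mean(vapply(p, function(i) mean(vapply(q, function(j) d[i, j],
                                                 numeric(1L))), numeric(1L)))
  dir2 <- mean(vapply(q, function(j) mean(vapply(p, function(i) d[i, j],
                                                 numeric(1L))), numeric(1L)))
  dir1 + dir2
}

# GDM by explicit per-edge classification.
oracle_gdm <- function(edges, assignment, retained, members,
                       mode = "incident") {
  e_intra <- 0L
  e_inter <- 0L
  if (length(edges) && nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      qual <- if (mode == "incident") (a %in% members) || (b %in% members)
              else (a %in% members) && (b %in% members)
      if (!qual) next
      if (!(assignment[[a]] %in% retained) ||
          !(assignment[[b]] %in% retained)) next
      if (assignment[[a]] == assignment[[b]]) e_intra <- e_intra + 1L
      else e_inter <- e_inter + 1L
    }
  }
  list(e_intra = e_intra, e_inter = e_inter,
       gdm = if (e_intra + e_inter > 0) e_intra / (e_intra + e_inter)
             else NA_real_)
}

# Betweenness by exhaustive enumeration of all simple paths (tiny graphs).
oracle_betweenness <- function(A) {
  nodes <- rownames(A)
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  all_paths <- function(from, to) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (nb in nodes[A[last, ] == 1L]) {
        if (!(nb %in% path)) grow(c(path, nb))
      }
    }
    grow(from)
    out
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      paths <- all_paths(nodes[i], nodes[j])
      if (length(paths) == 0L) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      inner <- unlist(lapply(shortest, function(p) p[-c(1L, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / sigma
      }
    }
  }
  btw
}

# Local clustering coefficient by triangle counting (0 for degree < 2).
oracle_local_cc <- function(A, v) {
  nbrs <- rownames(A)[A[v, ] == 1L]
  k <- length(nbrs)
  if (k < 2L) return(0)
  tri <- 0L
  for (x in seq_len(k - 1L)) {
    for (y in (x + 1L):k) {
      if (A[nbrs[x], nbrs[y]] == 1L) tri <- tri + 1L
    }
  }
  tri / (k * (k - 1L) / 2L)
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[ord[r]] * m / r)
    adj[ord[r]] <- val
    prev <- val
  }
  adj
}

# One-sided KS statistic by a direct scan over both samples' points.
oracle_ks_stat <- function(a, b, alternative) {
  pts <- sort(c(a, b))
  fa <- vapply(pts, function(x) mean(a <= x), numeric(1L))
  fb <- vapply(pts, function(x) mean(b <= x), numeric(1L))
  if (alternative == "less") max(c(fa - fb, 0)) else max(c(fb - fa, 0))
}

# Upper-tail hypergeometric probability by direct summation of dhyper.
oracle_hyper_tail <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(stats::dhyper(k:hi, K, N - K, n))
}

# Modularity from the definition (fractions of edge-end placements).
oracle_modularity <- function(edges, assignment) {
  m <- nrow(edges)
  ids <- unique(assignment)
  q <- 0
  for (id in ids) {
    inside <- sum(assignment[edges[, 1L]] == id &
                  assignment[edges[, 2L]] == id)
    deg <- sum(assignment[edges[, 1L]] == id) +
      sum(assignment[edges[, 2L]] == id)
    q <- q + inside / m - (deg / (2 * m))^2
  }
  q
}
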