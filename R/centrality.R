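# Node centralities, background means, and one-tailed group comparisons.

#' Compute the four node centralities
#'
#' Returns degree, betweenness, closeness and eigenvector centrality for
#' every node. Conventions:
#' \itemize{
#'   \item betweenness is unnormalized, with the standard splitting over
#'     equal-length shortest paths;
#'   \item closeness uses the package's disconnected-pair convention:
#'     distances to unreachable nodes are filled with the network's maximum
#'     finite shortest path, then `closeness = (n-1) / sum(d)` — so it is
#'     defined network-wide and lies in (0, 1];
#'   \item eigenvector centrality comes from power iteration on the full
#'     adjacency (shifted by the identity so periodic/bipartite components
#'     converge), max-normalized; on disconnected graphs nodes off the
#'     dominant component may score ~0.
#' }
#'
#' @param net a `ppi_network` with >= 2 nodes and >= 1 edge.
#' @param sp optional precomputed [sp_matrix()] (reused for closeness).
#' @return A `data.frame` with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`, one row per network node.
#' @export
compute_centralities <- function(net, sp = NULL) {
  if (n_nodes(net) < 2L || n_edges(net) < 1L) {
    stop("network must have at least 2 nodes and 1 edge")
  }
  g <- net$graph
  nodes <- network_nodes(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (is.null(sp)) sp <- sp_matrix(net)
  n <- length(nodes)
  clo <- (n - 1) / rowSums(sp$d)
  eig <- power_iteration_eigen(g)
  data.frame(node = nodes,
             degree = as.numeric(deg[nodes]),
             betweenness = as.numeric(btw[nodes]),
             closeness = as.numeric(clo[nodes]),
             eigenvector = as.numeric(eig[nodes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Power iteration for the dominant adjacency eigenvector, max-normalized.
# Iterates x <- (A + I) x: the identity shift leaves eigenvectors unchanged
# but makes all eigenvalues of a connected component positive, so bipartite
# components cannot oscillate.
power_iteration_eigen <- function(g, tol = 1e-10, max_iter = 1e4L) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    ax <- numeric(n)
    agg <- rowsum(c(x[el[, 2L]], x[el[, 1L]]), c(el[, 1L], el[, 2L]))
    ax[as.integer(rownames(agg))] <- agg[, 1L]
    xn <- x + ax
    xn <- xn / max(xn)
    if (max(abs(xn - x)) < tol) {
      x <- xn
      break
    }
    x <- xn
  }
  stats::setNames(x, igraph::V(g)$name)
}

#' Background mean of a centrality
#'
#' Arithmetic mean of a centrality measure over all nodes of the network —
#' the whole-network reference level group comparisons are read against.
#'
#' @param tab a centrality table from [compute_centralities()].
#' @param measure one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"eigenvector"`.
#' @return Numeric scalar.
#' @export
background_mean <- function(tab, measure) {
  if (!measure %in% names(tab)) stop("unknown measure '", measure, "'")
  mean(tab[[measure]])
}

#' One-tailed two-group comparison of a centrality
#'
#' Welch (unequal-variance) two-sample t-test on per-node centrality values
#' of two mapped gene sets, one-sided in the stated direction. The
#' FDR-adjusted `q` is `NA` here; adjust across the family of comparisons
#' with [fdr_adjust()].
#'
#' @param tab a centrality table from [compute_centralities()].
#' @param set_a,set_b `mapped_gene_set`s with >= 2 in-network genes each.
#' @param measure centrality column name.
#' @param direction `"greater"` tests mean(a) > mean(b); `"less"` the
#'   reverse.
#' @return One-row `data.frame`: `group_a`, `group_b`, `measure`,
#'   `direction`, `n_a`, `n_b`, `t_statistic`, `p`, `q` (NA).
#' @export
compare_groups <- function(tab, set_a, set_b, measure,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!measure %in% names(tab)) stop("unknown measure '", measure, "'")
  va <- tab[[measure]][tab$node %in% set_members(set_a, tab$node)]
  vb <- tab[[measure]][tab$node %in% set_members(set_b, tab$node)]
  if (length(va) < 2L || length(vb) < 2L) {
    stop("both groups need at least 2 in-network genes (got ",
         length(va), " and ", length(vb), ")")
  }
  tt <- stats::t.test(va, vb, alternative = direction, var.equal = FALSE)
  data.frame(group_a = set_label(set_a), group_b = set_label(set_b),
             measure = measure, direction = direction,
             n_a = length(va), n_b = length(vb),
             t_statistic = unname(tt$statistic), p = tt$p.value, q = NA_real_,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input. The family is
#' whatever vector is passed in one call.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length.
#' @export
fdr_adjust <- function(pvalues) {
  stopifnot_prob(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}
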