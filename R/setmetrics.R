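# Shortest-path machinery and the set-level distance measures.
#
# Distances are unweighted shortest paths (BFS). Pairs of nodes with no
# connecting path get the network's maximum finite shortest path as their
# distance, so every measure below is defined network-wide even on
# disconnected graphs. The fill value is computed once over the whole network
# and cached; it is never recomputed per set.

#' All-pairs shortest-path matrix with disconnected-pair fill
#'
#' @param net a `ppi_network` with at least 2 nodes and 1 edge.
#' @return Object of class `sp_matrix`: `d` a dense symmetric matrix of
#'   path lengths (dimnames = node symbols) and `max_finite_sp`, the maximum
#'   finite shortest path, used as the distance for disconnected pairs.
#' @export
sp_matrix <- function(net) {
  if (n_nodes(net) < 2L) stop("network must have at least 2 nodes")
  if (n_edges(net) == 0L) {
    stop("network has no edges: maximum finite shortest path is undefined")
  }
  d <- igraph::distances(net$graph)
  max_fin <- max(d[is.finite(d)])
  d[!is.finite(d)] <- max_fin
  structure(list(d = d, max_finite_sp = max_fin), class = "sp_matrix")
}

#' @export
print.sp_matrix <- function(x, ...) {
  cat(sprintf("<sp_matrix> %d nodes, max finite SP = %g\n",
              nrow(x$d), x$max_finite_sp))
  invisible(x)
}

#' Set clustering coefficient
#'
#' Aggregates the local clustering coefficient over a set's in-network
#' members. `node_average` (default) computes each member's local CC on the
#' full network (nodes of degree < 2 contribute 0) and averages;
#' `induced_subgraph` computes the same statistic on the subgraph induced by
#' the members.
#'
#' @param net a `ppi_network`.
#' @param s a `mapped_gene_set`, `gene_set`, or character vector.
#' @param mode `"node_average"` or `"induced_subgraph"`.
#' @return Mean local clustering coefficient (numeric scalar).
#' @export
set_clustering_coefficient <- function(net, s,
                                       mode = c("node_average",
                                                "induced_subgraph")) {
  mode <- match.arg(mode)
  members <- set_members(s, network_nodes(net))
  if (length(members) == 0L) {
    stop("set '", set_label(s), "' has no in-network members")
  }
  if (mode == "node_average") {
    cc <- igraph::transitivity(net$graph, type = "local", vids = members,
                               isolates = "zero")
  } else {
    sub <- igraph::induced_subgraph(net$graph, members)
    cc <- igraph::transitivity(sub, type = "local", isolates = "zero")
  }
  mean(cc)
}

#' Intra-set distance (IAD)
#'
#' Mean shortest-path distance over all ordered pairs of distinct in-network
#' members of a set: `IAD = 1/(N(N-1)) * sum_{i != j} d_ij`. By symmetry this
#' equals the unordered-pair average. Requires at least 2 in-network genes.
#'
#' @param sp an [sp_matrix()].
#' @param s a `mapped_gene_set`, `gene_set`, or character vector.
#' @return List of class `iad_result`: `set_name`, `n_used`, `iad`.
#' @export
intra_set_distance <- function(sp, s) {
  members <- set_members(s, rownames(sp$d))
  n <- length(members)
  if (n < 2L) {
    stop("IAD undefined: set '", set_label(s),
         "' has fewer than 2 in-network genes")
  }
  block <- sp$d[members, members, drop = FALSE]
  iad <- sum(block) / (n * (n - 1))   # diagonal is zero
  structure(list(set_name = set_label(s), n_used = n, iad = iad),
            class = "iad_result")
}

#' Inter-set distance (IED)
#'
#' For sets S_p and S_q, each gene i of S_p gets the mean distance to all
#' genes of S_q (a gene shared by both sets contributes its zero
#' self-distance — there is no i != j exclusion across sets); IED is the sum
#' of the two directional means. Both directional means equal the grand mean
#' of the cross-distance block, so IED = 2 x grand mean; the identity is
#' asserted at run time.
#'
#' @param sp an [sp_matrix()].
#' @param sp_set,sq_set `mapped_gene_set`s (or gene sets / character
#'   vectors), both with at least one in-network member.
#' @return List of class `ied_result`: `set_p`, `set_q`, `n_p`, `n_q`,
#'   `mean_p_to_q`, `mean_q_to_p`, `ied`.
#' @export
inter_set_distance <- function(sp, sp_set, sq_set) {
  nodes <- rownames(sp$d)
  p <- set_members(sp_set, nodes)
  q <- set_members(sq_set, nodes)
  if (length(p) == 0L || length(q) == 0L) {
    stop("IED undefined: a set has no in-network genes")
  }
  block <- sp$d[p, q, drop = FALSE]
  mean_p_to_q <- mean(rowMeans(block))   # mean over i of D_i^{Sq}
  mean_q_to_p <- mean(colMeans(block))   # mean over j of D_j^{Sp}
  stopifnot(isTRUE(all.equal(mean_p_to_q, mean_q_to_p)))
  structure(list(set_p = set_label(sp_set), set_q = set_label(sq_set),
                 n_p = length(p), n_q = length(q),
                 mean_p_to_q = mean_p_to_q, mean_q_to_p = mean_q_to_p,
                 ied = mean_p_to_q + mean_q_to_p),
            class = "ied_result")
}
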