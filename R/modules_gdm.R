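# Module detection by deterministic multi-step greedy modularity
# maximization, the >= min_size retention filter, and the
# genset-distribution-in-modules (GDM) statistic.

#' Detect network modules by multi-step greedy modularity maximization
#'
#' Deterministic agglomerative scheme: start from singleton communities and
#' sweep repeatedly; in each sweep compute the modularity gain of merging
#' every pair of edge-connected communities, then apply every positive-gain
#' merge that is a mutual best match — each community's highest-gain partner
#' (ties broken by the lexicographically smallest partner label, where a
#' community's label is its smallest member symbol), accepted only when the
#' preference is reciprocal. Mutual-best pairs are disjoint, so all merges
#' in a sweep commute and their gains add exactly; the globally best pair is
#' always mutual, so every sweep makes progress. Stops when no merge has
#' positive gain. Because the algorithm only merges edge-connected
#' communities it
#' runs independently per connected component; isolated nodes remain
#' singleton modules. Modules with at least `min_size` nodes are marked
#' retained.
#'
#' The exact multi-step greedy published elsewhere is not reproduced
#' line-for-line; any external partitioner's output can be substituted via
#' [import_partition()].
#'
#' @param net a non-empty `ppi_network`.
#' @param min_size retention threshold (default 30 genes).
#' @param seed accepted for interface uniformity; the algorithm is fully
#'   deterministic and does not consume randomness.
#' @return Object of class `module_partition`: `assignment` (named integer
#'   vector node -> module id, ids ordered by decreasing module size),
#'   `retained` (ids passing the filter), `min_size`, `modularity` (Q of the
#'   full partition), `sizes`.
#' @export
detect_modules <- function(net, min_size = 30L, seed = 1L) {
  n <- n_nodes(net)
  if (n == 0L) stop("empty network")
  nodes <- network_nodes(net)
  m <- n_edges(net)
  comm <- seq_len(n)          # community index of each node
  label <- nodes              # community label = smallest member symbol
  if (m > 0L) {
    el <- igraph::as_edgelist(net$graph, names = FALSE)
    repeat {
      ca <- comm[el[, 1L]]
      cb <- comm[el[, 2L]]
      deg_c <- tabulate(c(ca, cb), nbins = n)
      a_frac <- deg_c / (2 * m)
      off <- ca != cb
      if (!any(off)) break
      pi_ <- pmin(ca, cb)[off]
      pj <- pmax(ca, cb)[off]
      key <- (pi_ - 1) * n + pj
      cnt <- table(key)
      keys <- as.numeric(names(cnt))
      ii <- ((keys - 1) %/% n) + 1
      jj <- keys - (ii - 1) * n
      gain <- as.numeric(cnt) / m - 2 * a_frac[ii] * a_frac[jj]
      pos <- gain > 1e-12
      if (!any(pos)) break
      ii <- ii[pos]; jj <- jj[pos]; gain <- gain[pos]
      # best positive-gain partner of each community, ties broken by the
      # lexicographically smallest partner label
      best <- rep(NA_integer_, n)
      best_gain <- rep(-Inf, n)
      consider <- function(c1, c2, g, k) {
        if (g > best_gain[c1] + 1e-12 ||
            (abs(g - best_gain[c1]) <= 1e-12 && !is.na(best[c1]) &&
             label[c2] < label[best[c1]])) {
          best_gain[c1] <<- g
          best[c1] <<- c2
        }
      }
      for (k in seq_along(gain)) {
        consider(ii[k], jj[k], gain[k], k)
        consider(jj[k], ii[k], gain[k], k)
      }
      mutual <- which(best[ii] == jj & best[jj] == ii)
      if (length(mutual) == 0L) break   # cannot happen: top pair is mutual
      for (k in mutual) {
        ci <- ii[k]; cj <- jj[k]
        keep <- if (label[ci] <= label[cj]) ci else cj
        drop <- if (keep == ci) cj else ci
        comm[comm == drop] <- keep
        label[keep] <- min(label[ci], label[cj])
      }
    }
  }
  finalize_partition(nodes, comm, label, net, min_size)
}

# Relabel communities 1..k by decreasing size (label as tiebreak) and build
# the module_partition object.
finalize_partition <- function(nodes, comm, label, net, min_size) {
  ids <- sort(unique(comm))
  sizes <- tabulate(match(comm, ids))
  ord <- order(-sizes, label[ids])
  new_id <- integer(max(ids))
  new_id[ids[ord]] <- seq_along(ids)
  assignment <- stats::setNames(new_id[comm], nodes)
  sizes_final <- as.integer(table(assignment))
  retained <- which(sizes_final >= min_size)
  structure(list(assignment = assignment,
                 retained = as.integer(retained),
                 min_size = as.integer(min_size),
                 modularity = partition_modularity(net, assignment),
                 sizes = sizes_final),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf(
    "<module_partition> %d modules (%d retained at >= %d genes), Q = %.4f\n",
    length(x$sizes), length(x$retained), x$min_size, x$modularity))
  invisible(x)
}

#' Modularity Q of a node-to-module assignment
#'
#' `Q = sum_c [ e_c / m - (deg_c / 2m)^2 ]` with `e_c` the number of edges
#' inside module `c`, `deg_c` its total degree and `m` the edge count.
#'
#' @param net a `ppi_network`.
#' @param assignment named vector (node -> module id) covering the network.
#' @return Numeric Q.
#' @export
partition_modularity <- function(net, assignment) {
  m <- n_edges(net)
  if (m == 0L) return(0)
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  ma <- assignment[el[, 1L]]
  mb <- assignment[el[, 2L]]
  ids <- sort(unique(assignment))
  within <- vapply(ids, function(id) sum(ma == id & mb == id), integer(1L))
  deg <- vapply(ids, function(id) sum(ma == id) + sum(mb == id), numeric(1L))
  sum(within / m - (deg / (2 * m))^2)
}

#' Import a module partition from a two-column TSV
#'
#' Lets an external partitioner (e.g. a published multi-step greedy
#' implementation) supply the module assignment; the size filter and Q are
#' recomputed here.
#'
#' @param path TSV with columns node, module_id (no header; `#` comments
#'   ignored).
#' @param net the `ppi_network` the partition must cover.
#' @param min_size retention threshold.
#' @return A `module_partition`.
#' @export
import_partition <- function(path, net, min_size = 30L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("node", "module_id"))
  nodes <- network_nodes(net)
  missing <- setdiff(nodes, df$node)
  if (length(missing)) {
    stop("partition does not cover the network (first missing node: '",
         missing[1L], "')")
  }
  df <- df[df$node %in% nodes, , drop = FALSE]
  if (anyDuplicated(df$node)) stop("node assigned to more than one module")
  comm <- match(df$module_id, sort(unique(df$module_id)))
  label <- vapply(sort(unique(comm)), function(id) min(df$node[comm == id]),
                  character(1L))
  ord <- match(nodes, df$node)
  finalize_partition(nodes, comm[ord], label, net, min_size)
}

#' Export a module partition to TSV
#'
#' @param part a `module_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_partition <- function(part, path) {
  writeLines(c("# node\tmodule_id",
               paste(names(part$assignment), part$assignment, sep = "\t")),
             path)
  invisible(path)
}

#' Genset-distribution in modules (GDM)
#'
#' `GDM = E_intra / (E_intra + E_inter)`: among a gene set's qualifying
#' edges, the fraction whose endpoints lie in the same network module.
#' `incident` mode (default) qualifies every network edge with at least one
#' endpoint in the set; `induced` mode requires both endpoints in the set.
#' Edges touching nodes outside retained modules are excluded from both
#' counts by default (counting them as "inter" would conflate small-module
#' membership with between-module placement); set
#' `include_unretained = TRUE` to count them as E_inter instead.
#'
#' @param net a `ppi_network`.
#' @param part a `module_partition` covering it.
#' @param s a `mapped_gene_set` (or gene set / character vector).
#' @param mode `"incident"` or `"induced"`.
#' @param include_unretained count edges touching unretained modules as
#'   E_inter (default FALSE: excluded entirely).
#' @return List of class `gdm_result`: `set_name`, `mode`, `e_intra`,
#'   `e_inter`, `gdm` (`NA` and `undefined = TRUE` when no edge qualifies).
#' @export
gdm <- function(net, part, s, mode = c("incident", "induced"),
                include_unretained = FALSE) {
  mode <- match.arg(mode)
  members <- set_members(s, network_nodes(net))
  if (length(members) == 0L) {
    stop("set '", set_label(s), "' has no in-network members")
  }
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  if (nrow(el) == 0L) {
    qual <- logical(0L); same <- logical(0L); both_ret <- logical(0L)
  } else {
    in_a <- el[, 1L] %in% members
    in_b <- el[, 2L] %in% members
    qual <- if (mode == "incident") in_a | in_b else in_a & in_b
    mod_a <- part$assignment[el[, 1L]]
    mod_b <- part$assignment[el[, 2L]]
    both_ret <- (mod_a %in% part$retained) & (mod_b %in% part$retained)
    same <- mod_a == mod_b
  }
  if (include_unretained) {
    e_intra <- sum(qual & same & both_ret)
    e_inter <- sum(qual & !(same & both_ret))
  } else {
    e_intra <- sum(qual & both_ret & same)
    e_inter <- sum(qual & both_ret & !same)
  }
  denom <- e_intra + e_inter
  structure(list(set_name = set_label(s), mode = mode,
                 e_intra = as.integer(e_intra), e_inter = as.integer(e_inter),
                 gdm = if (denom > 0) e_intra / denom else NA_real_,
                 undefined = denom == 0),
            class = "gdm_result")
}
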