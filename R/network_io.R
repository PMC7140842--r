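# Loading, cleaning and summarizing undirected PPI networks.

#' Construct a PPI network from an edge table
#'
#' Builds an undirected simple graph over gene symbols. Self-loops are
#' dropped, reversed duplicates `(a,b)`/`(b,a)` are collapsed to a single
#' edge, and symbols are case-preserved (comparison is exact string match).
#' Disconnected components are retained: the analysis never restricts to the
#' largest component.
#'
#' @param edges two-column character matrix or data frame of interacting
#'   gene symbols (additional columns ignored).
#' @param nodes optional character vector of extra (possibly isolated) nodes
#'   to declare in addition to the edge endpoints.
#' @param provenance free-text label recording the source file and filters.
#' @return An object of class `ppi_network` wrapping an `igraph` graph.
#' @seealso [load_edge_list()], [summarize_network()]
#' @export
ppi_network <- function(edges, nodes = character(0L), provenance = "") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L || nrow(edges) == 0L) {
    a <- character(0L)
    b <- character(0L)
  } else {
    a <- as.character(edges[, 1L])
    b <- as.character(edges[, 2L])
  }
  keep <- a != b                     # no self-loops
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b) # canonical unordered pair
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  verts <- sort(unique(c(lo, hi, as.character(nodes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  structure(list(graph = g, provenance = provenance), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges", n_nodes(x), n_edges(x)))
  if (nzchar(x$provenance)) cat("  [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Network accessors
#'
#' @param net a `ppi_network`.
#' @return `network_nodes()` the character vector of node symbols;
#'   `network_edges()` a two-column character matrix of canonically ordered
#'   edges; `n_nodes()`/`n_edges()` counts.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph, names = TRUE)
  if (nrow(el) == 0L) {
    return(matrix(character(0L), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  lo <- pmin(el[, 1L], el[, 2L])
  hi <- pmax(el[, 1L], el[, 2L])
  ord <- order(lo, hi)
  matrix(c(lo[ord], hi[ord]), ncol = 2L, dimnames = list(NULL, c("a", "b")))
}

#' @rdname network_nodes
#' @export
n_nodes <- function(net) as.integer(igraph::vcount(net$graph))

#' @rdname network_nodes
#' @export
n_edges <- function(net) as.integer(igraph::ecount(net$graph))

#' Load an undirected PPI network from a tab-separated edge list
#'
#' Reads a TSV edge list (columns: geneA, geneB, and optionally a numeric
#' confidence score), ignoring `#`-prefixed comment lines. Self-loops are
#' dropped and duplicate/reversed edges collapsed. When `score_threshold` is
#' given, edges with score strictly below the threshold are removed and ties
#' are kept ("scores less than" the cutoff are discarded). The threshold is
#' interpreted on the file's own scale — pass `0.6` for a normalized file or
#' `600` for a raw String-style 0–1000 export; no rescaling is performed.
#'
#' @param path path to the edge-list TSV.
#' @param score_threshold optional numeric; edges with score `<` threshold
#'   are removed.
#' @param score_column 1-based column index of the score (default 3).
#' @param node_file optional path to a one-symbol-per-line file declaring
#'   additional isolated nodes. By default the node set is the union of
#'   retained edge endpoints only.
#' @return A [ppi_network()].
#' @export
load_edge_list <- function(path, score_threshold = NULL, score_column = 3L,
                           node_file = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no edges in '", path, "'")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- lineno[which(nf < 2L)[1L]]
    stop("malformed edge-list line ", bad,
         ": expected at least 2 tab-separated fields")
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  if (!is.null(score_threshold)) {
    if (any(nf < score_column)) {
      bad <- lineno[which(nf < score_column)[1L]]
      stop("line ", bad, ": no score field in column ", score_column)
    }
    sc <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, character(1L), score_column)))
    if (anyNA(sc)) {
      bad <- lineno[which(is.na(sc))[1L]]
      stop("line ", bad, ": score is not numeric")
    }
    keep_e <- sc >= score_threshold
    a <- a[keep_e]; b <- b[keep_e]
  }
  extra <- character(0L)
  if (!is.null(node_file)) {
    extra <- trimws(readLines(node_file, warn = FALSE))
    extra <- extra[nzchar(extra) & !startsWith(extra, "#")]
  }
  prov <- paste0(basename(path),
                 if (!is.null(score_threshold))
                   sprintf(" [score >= %s]", format(score_threshold)) else "")
  ppi_network(cbind(a, b), nodes = extra, provenance = prov)
}

#' Write a network back to a canonical edge-list TSV
#'
#' Edges are written in canonical (lexicographically sorted) order so that a
#' load/write/load round trip is byte-stable.
#'
#' @param net a `ppi_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- network_edges(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# geneA\tgeneB", con)
  if (nrow(el) > 0L) writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Summarize a network
#'
#' @param net a `ppi_network`.
#' @return list with `n_nodes`, `n_edges`, and `max_finite_sp` — the maximum
#'   shortest-path length over all connected node pairs (`NA` when no two
#'   nodes are connected).
#' @export
summarize_network <- function(net) {
  d <- igraph::distances(net$graph)
  fin <- d[is.finite(d) & d > 0]
  list(n_nodes = n_nodes(net),
       n_edges = n_edges(net),
       max_finite_sp = if (length(fin)) max(fin) else NA_real_)
}
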