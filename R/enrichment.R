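# Fisher-test functional enrichment with term-size and evidence filters,
# and the module-function intersection analysis.

#' Load a gene-to-term annotation table
#'
#' Four-column TSV: gene symbol, term id, term name, evidence code. Filter
#' order matches the enrichment protocol: records with excluded evidence
#' codes (default IEA, "inferred from electronic annotation") are dropped
#' first, then genes are restricted to the declared background, duplicate
#' (gene, term) pairs are collapsed, and finally terms whose
#' within-background size falls outside `[min_term, max_term]`
#' (boundary-inclusive) are dropped. Ontology propagation is not performed;
#' pre-propagate upstream if desired.
#'
#' @param path annotation TSV (no header; `#` comments ignored).
#' @param min_term,max_term inclusive term-size bounds within the background
#'   (defaults 30 and 300).
#' @param excluded_evidence evidence codes to drop (default `"IEA"`).
#' @param background character vector of background genes (typically all
#'   genes present in the network).
#' @return Object of class `annotation_table`: `records` (gene, term_id,
#'   term_name), `term_sizes` (named integer), `term_names`, `background`.
#' @export
load_annotations <- function(path, min_term = 30L, max_term = 300L,
                             excluded_evidence = "IEA", background) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("background must be non-empty")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- lineno[which(nf < 4L)[1L]]
    stop("annotation line ", bad, ": expected 4 tab-separated fields")
  }
  df <- data.frame(gene = vapply(fields, `[[`, character(1L), 1L),
                   term_id = vapply(fields, `[[`, character(1L), 2L),
                   term_name = vapply(fields, `[[`, character(1L), 3L),
                   evidence = vapply(fields, `[[`, character(1L), 4L),
                   stringsAsFactors = FALSE)
  annotation_table(df, min_term = min_term, max_term = max_term,
                   excluded_evidence = excluded_evidence,
                   background = background)
}

#' @rdname load_annotations
#' @param records data frame with columns gene, term_id, term_name,
#'   evidence (in-memory alternative to `path`).
#' @export
annotation_table <- function(records, min_term = 30L, max_term = 300L,
                             excluded_evidence = "IEA", background) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("background must be non-empty")
  df <- records
  df <- df[!(df$evidence %in% excluded_evidence), , drop = FALSE]  # IEA first
  df <- df[df$gene %in% background, , drop = FALSE]
  df <- df[!duplicated(paste(df$gene, df$term_id, sep = "\r")), , drop = FALSE]
  sizes <- table(df$term_id)
  ok_terms <- names(sizes)[sizes >= min_term & sizes <= max_term]
  df <- df[df$term_id %in% ok_terms, , drop = FALSE]
  term_sizes <- as.integer(table(df$term_id)[ok_terms])
  names(term_sizes) <- ok_terms
  tn <- df$term_name[!duplicated(df$term_id)]
  names(tn) <- df$term_id[!duplicated(df$term_id)]
  structure(list(records = df[, c("gene", "term_id", "term_name")],
                 term_sizes = term_sizes,
                 term_names = tn,
                 background = background),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf(
    "<annotation_table> %d terms over %d background genes (%d records)\n",
    length(x$term_sizes), length(x$background), nrow(x$records)))
  invisible(x)
}

#' Fisher-test over-representation enrichment
#'
#' Per term: one-sided Fisher exact p-value for over-representation on the
#' 2x2 table (k, n-k, K-k, N-K-n+k) where `k` is the query/term overlap,
#' `n` the query size within the background, `K` the term size and `N` the
#' background size. Benjamini-Hochberg adjustment is applied across all
#' tested terms; rows with `q < q_threshold` are returned sorted by
#' ascending p. The full unfiltered table is attached as
#' `attr(result, "all")`.
#'
#' @param query a `mapped_gene_set` (or gene set / character vector); its
#'   in-network genes are intersected with the annotation background.
#' @param ann an [annotation_table()].
#' @param q_threshold FDR cutoff (default 0.05).
#' @return `data.frame` with columns `term_id`, `term_name`, `k`, `n`, `K`,
#'   `N`, `p`, `q`.
#' @export
fisher_enrichment <- function(query, ann, q_threshold = 0.05) {
  qg <- set_members(query, ann$background)
  n <- length(qg)
  if (n == 0L) stop("empty query after restriction to the background")
  N <- length(ann$background)
  terms <- names(ann$term_sizes)
  K <- as.integer(ann$term_sizes)
  k <- vapply(terms, function(t) {
    sum(ann$records$gene[ann$records$term_id == t] %in% qg)
  }, integer(1L))
  # upper tail including the observed count
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- fdr_adjust(p)
  res <- data.frame(term_id = terms,
                    term_name = unname(ann$term_names[terms]),
                    k = k, n = n, K = K, N = N, p = p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  out <- res[res$q < q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- res
  out
}

#' Retained modules containing several gene sets
#'
#' Reports every retained module that contains at least
#' `min_genes_per_set` genes from each of at least `min_sets` distinct
#' input sets.
#'
#' @param part a `module_partition`.
#' @param sets list of `mapped_gene_set`s (or gene sets).
#' @param min_sets minimum number of contributing sets (default 2).
#' @param min_genes_per_set minimum genes a set must place in the module to
#'   count as contributing (default 1).
#' @return `data.frame` with columns `module` (id) and `sets` (list column
#'   of contributing set names); zero rows when none qualify.
#' @export
modules_with_min_sets <- function(part, sets, min_sets = 2L,
                                  min_genes_per_set = 1L) {
  nodes <- names(part$assignment)
  rows <- lapply(part$retained, function(mod) {
    mod_nodes <- nodes[part$assignment == mod]
    contrib <- vapply(sets, function(s) {
      length(set_members(s, mod_nodes)) >= min_genes_per_set
    }, logical(1L))
    labs <- vapply(sets, set_label, character(1L))
    if (sum(contrib) >= min_sets) {
      list(module = mod, sets = labs[contrib])
    } else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  data.frame(module = vapply(rows, `[[`, integer(1L), "module"),
             sets = I(lapply(rows, `[[`, "sets")))
}

#' Intersection of two enrichment result lists
#'
#' Terms significant in both analyses; the combined p-value of a shared
#' term is the larger of its two adjusted p-values (the conservative
#' combination). Sorted ascending by combined p.
#'
#' @param results_a,results_b `data.frame`s from [fisher_enrichment()].
#' @return `data.frame` with `term_id`, `term_name`, `q_a`, `q_b`,
#'   `combined_p`.
#' @export
term_intersection <- function(results_a, results_b) {
  common <- intersect(results_a$term_id, results_b$term_id)
  ia <- match(common, results_a$term_id)
  ib <- match(common, results_b$term_id)
  out <- data.frame(term_id = common,
                    term_name = results_a$term_name[ia],
                    q_a = results_a$q[ia],
                    q_b = results_b$q[ib],
                    combined_p = pmax(results_a$q[ia], results_b$q[ib]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$combined_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
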