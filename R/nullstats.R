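# Random-gene-set null distributions, one-tailed two-sample KS tests and
# permutation p-values.

#' Sample uniform random gene sets
#'
#' Draws `b` gene sets, each a uniform without-replacement sample of
#' `set_size` symbols from a gene universe (e.g. all official symbols, or
#' the network's node set). Reproducible given `seed`.
#'
#' @param universe character vector of candidate symbols.
#' @param set_size genes per random set (default 120).
#' @param b number of sets (default 1000).
#' @param seed integer RNG seed.
#' @return Named list of [gene_set()]s (`R0001`, `R0002`, ...).
#' @export
sample_random_sets <- function(universe, set_size = 120L, b = 1000L,
                               seed = 1L) {
  universe <- unique(as.character(universe))
  if (set_size > length(universe)) {
    stop("set_size (", set_size, ") exceeds universe size (",
         length(universe), ")")
  }
  with_seed(seed, {
    sets <- lapply(seq_len(b), function(i) {
      gene_set(sprintf("R%04d", i), sample(universe, set_size))
    })
    names(sets) <- vapply(sets, `[[`, character(1L), "name")
    sets
  })
}

#' Null distribution of a set-level measure over random gene sets
#'
#' Maps each random set onto the network and evaluates one measure.
#' Undefined evaluations (fewer than 2 in-network genes for IAD, no
#' qualifying edge for GDM, no in-network gene at all) are dropped and
#' counted, never imputed.
#'
#' @param net a `ppi_network`.
#' @param sp an [sp_matrix()] (needed for `iad`/`ied`; may be NULL for
#'   `cc`/`gdm`).
#' @param part a `module_partition` (needed for `gdm`; may be NULL
#'   otherwise).
#' @param random_sets list of gene sets, e.g. from [sample_random_sets()].
#' @param measure one of `"cc"`, `"iad"`, `"ied"`, `"gdm"`.
#' @param reference_set for `ied`: the fixed set distances are measured to.
#' @param gdm_mode,cc_mode passed through to [gdm()] /
#'   [set_clustering_coefficient()].
#' @return Object of class `null_distribution`: `measure`, `b`, `set_size`
#'   (nominal input size), `values` (defined evaluations), `n_dropped`,
#'   `effective_sizes` (post-mapping in-network sizes).
#' @export
null_distribution <- function(net, sp = NULL, part = NULL, random_sets,
                              measure = c("cc", "iad", "ied", "gdm"),
                              reference_set = NULL,
                              gdm_mode = "incident",
                              cc_mode = "node_average") {
  measure <- match.arg(measure)
  if (measure %in% c("iad", "ied") && is.null(sp)) {
    stop("measure '", measure, "' needs an sp_matrix")
  }
  if (measure == "gdm" && is.null(part)) {
    stop("measure 'gdm' needs a module_partition")
  }
  if (measure == "ied" && is.null(reference_set)) {
    stop("measure 'ied' needs a reference_set")
  }
  ref <- if (measure == "ied") {
    if (inherits(reference_set, "mapped_gene_set")) reference_set
    else map_to_network(reference_set, net)
  } else NULL
  eval_one <- function(s) {
    ms <- suppressWarnings(map_to_network(s, net))
    tryCatch(switch(measure,
      cc  = set_clustering_coefficient(net, ms, mode = cc_mode),
      iad = intra_set_distance(sp, ms)$iad,
      ied = inter_set_distance(sp, ms, ref)$ied,
      gdm = gdm(net, part, ms, mode = gdm_mode)$gdm),
      error = function(e) NA_real_)
  }
  vals <- vapply(random_sets, eval_one, numeric(1L))
  eff <- vapply(random_sets, function(s) {
    length(intersect(if (inherits(s, "gene_set")) s$genes else s,
                     network_nodes(net)))
  }, integer(1L))
  ok <- !is.na(vals)
  if (!any(ok)) stop("all ", length(vals), " null evaluations undefined")
  structure(list(measure = measure,
                 b = length(random_sets),
                 set_size = if (inherits(random_sets[[1L]], "gene_set"))
                   length(random_sets[[1L]]$genes) else NA_integer_,
                 values = unname(vals[ok]),
                 n_dropped = sum(!ok),
                 effective_sizes = unname(eff)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %s: %d values (%d dropped), median = %.4g\n",
    x$measure, length(x$values), x$n_dropped, stats::median(x$values)))
  invisible(x)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' For `alternative = "less"` (first sample stochastically smaller) the
#' statistic is `D = max(F_a - F_b)` over the pooled sample points; for
#' `"greater"` it is `max(F_b - F_a)`. The one-sided asymptotic p-value is
#' `exp(-2 m n / (m + n) * D^2)`, capped at 1.
#'
#' @param sample_a,sample_b numeric vectors (each non-empty); `sample_b`
#'   may also be a `null_distribution` (its values are used).
#' @param alternative `"less"` or `"greater"` for the first sample relative
#'   to the second.
#' @return List of class `np_test`: `statistic`, `p`, `alternative`,
#'   `method = "ks_one_sided"`.
#' @export
ks_one_sided <- function(sample_a, sample_b,
                         alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (inherits(sample_a, "null_distribution")) sample_a <- sample_a$values
  if (inherits(sample_b, "null_distribution")) sample_b <- sample_b$values
  if (length(sample_a) < 1L || length(sample_b) < 1L) {
    stop("both samples must be non-empty")
  }
  m <- length(sample_a)
  n <- length(sample_b)
  pts <- sort(unique(c(sample_a, sample_b)))
  fa <- stats::ecdf(sample_a)(pts)
  fb <- stats::ecdf(sample_b)(pts)
  d <- if (alternative == "less") max(fa - fb) else max(fb - fa)
  d <- max(d, 0)
  p <- min(1, exp(-2 * m * n / (m + n) * d^2))
  structure(list(statistic = d, p = p, alternative = alternative,
                 method = "ks_one_sided"),
            class = "np_test")
}

#' Permutation p-value against a null distribution
#'
#' Add-one convention: `p = (1 + #extreme) / (1 + B)` where `#extreme`
#' counts null values as or more extreme than the observation in the stated
#' direction. Never returns 0.
#'
#' @param observed observed statistic (numeric scalar).
#' @param null a `null_distribution` or numeric vector of null values.
#' @param alternative `"less"`: extreme means `null <= observed`;
#'   `"greater"`: `null >= observed`.
#' @return List of class `np_test`: `statistic` (= observed), `p`,
#'   `alternative`, `method = "permutation"`.
#' @export
permutation_p <- function(observed, null,
                          alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  vals <- if (inherits(null, "null_distribution")) null$values else null
  if (length(vals) < 1L) stop("null distribution is empty")
  extreme <- if (alternative == "less") sum(vals <= observed)
             else sum(vals >= observed)
  structure(list(statistic = observed,
                 p = (1 + extreme) / (1 + length(vals)),
                 alternative = alternative, method = "permutation"),
            class = "np_test")
}

#' @export
print.np_test <- function(x, ...) {
  cat(sprintf("<np_test> %s (%s): statistic = %.4g, p = %.4g\n",
              x$method, x$alternative, x$statistic, x$p))
  invisible(x)
}
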