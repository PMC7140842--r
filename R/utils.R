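#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state after.
# All randomized functions in the package route through this; there is no
# hidden global random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Extract member symbols of a set-like object, restricted to `available`.
# Accepts a mapped_gene_set (uses its in_network slot), a gene_set, or a bare
# character vector.
set_members <- function(s, available) {
  genes <- if (inherits(s, "mapped_gene_set")) {
    s$in_network
  } else if (inherits(s, "gene_set")) {
    s$genes
  } else {
    as.character(s)
  }
  intersect(genes, available)
}

set_label <- function(s) {
  if (inherits(s, "mapped_gene_set")) s$origin
  else if (inherits(s, "gene_set")) s$name
  else "<character>"
}

stopifnot_prob <- function(p, what = "p-value") {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop(what, " outside [0, 1]")
  }
  invisible(p)
}
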