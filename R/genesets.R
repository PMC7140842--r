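# Gene-set containers: GMT parsing, symbol normalization, merging, and
# mapping onto a network.

#' Construct a gene set
#'
#' @param name set label.
#' @param genes character vector of symbols; duplicates are collapsed.
#' @return Object of class `gene_set` with fields `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) < 1L) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name)[1L], genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Parse a GMT gene-set file
#'
#' Broad-dialect GMT: one set per line, tab-separated
#' `name <TAB> description <TAB> gene <TAB> gene ...`. Within-line duplicate
#' genes are collapsed.
#'
#' @param path path to the GMT file.
#' @return Named list of [gene_set()] objects.
#' @export
parse_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1L]]
    stop("GMT line ", bad, ": expected at least 3 tab-separated fields")
  }
  nms <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name '", nms[duplicated(nms)][1L], "' in '",
         path, "'")
  }
  sets <- lapply(fields, function(f) gene_set(f[[1L]], f[-c(1L, 2L)]))
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of `gene_set` objects.
#' @param path output path.
#' @param descriptions optional character vector of descriptions (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(s, d) {
    paste(c(s$name, d, s$genes), collapse = "\t")
  }, sets, descriptions)
  writeLines(lines, path)
  invisible(path)
}

#' Load a two-column alias table
#'
#' TSV with columns `alias`, `official`. An alias mapping to more than one
#' distinct official symbol is an error.
#'
#' @param path path to the TSV (no header; `#` comments ignored).
#' @return Named character vector `alias -> official`.
#' @export
load_alias_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("alias", "official"))
  as_alias_map(df)
}

as_alias_map <- function(alias_table) {
  if (is.null(alias_table) || length(alias_table) == 0L) {
    return(stats::setNames(character(0L), character(0L)))
  }
  if (is.data.frame(alias_table)) {
    al <- as.character(alias_table[[1L]])
    of <- as.character(alias_table[[2L]])
  } else {
    al <- names(alias_table)
    of <- as.character(alias_table)
  }
  dup_pair <- duplicated(paste(al, of, sep = "\r"))
  al <- al[!dup_pair]; of <- of[!dup_pair]
  if (anyDuplicated(al)) {
    stop("alias '", al[duplicated(al)][1L],
         "' maps to multiple official symbols")
  }
  stats::setNames(of, al)
}

#' Normalize gene symbols through an alias table
#'
#' Every symbol with an entry in the alias table is replaced by its official
#' symbol (emulating HGNC normalization); symbols without an entry are kept
#' verbatim — an alias table cannot tell an already-official symbol from an
#' unknown one. Post-mapping duplicates are collapsed.
#'
#' @param sets list of `gene_set` objects (or a single one).
#' @param alias_table two-column data frame (alias, official) or named
#'   character vector; see [load_alias_table()].
#' @return Sets of the same shape with normalized membership.
#' @export
normalize_symbols <- function(sets, alias_table) {
  map <- as_alias_map(alias_table)
  single <- inherits(sets, "gene_set")
  if (single) sets <- list(sets)
  n_mapped <- 0L
  out <- lapply(sets, function(s) {
    hit <- s$genes %in% names(map)
    n_mapped <<- n_mapped + sum(hit)
    genes <- s$genes
    genes[hit] <- unname(map[genes[hit]])
    gene_set(s$name, genes)
  })
  if (n_mapped > 0L) message("normalize_symbols: mapped ", n_mapped,
                             " aliased symbol(s)")
  names(out) <- vapply(out, `[[`, character(1L), "name")
  if (single) out[[1L]] else out
}

#' Merge gene sets into one union set
#'
#' @param sets list of `gene_set` objects.
#' @param new_name label of the merged set.
#' @return A [gene_set()] containing the deduplicated union of all members.
#' @export
merge_sets <- function(sets, new_name) {
  if (length(sets) < 1L) stop("merge_sets: need at least one input set")
  gene_set(new_name, unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))
}

#' Genes recurring across several sets
#'
#' @param sets list of `gene_set` objects.
#' @param min_times minimum number of distinct sets a symbol must appear in
#'   (must be >= 2).
#' @return Character vector of recurrent symbols (sorted).
#' @export
recurrence_count <- function(sets, min_times) {
  if (min_times < 2L) stop("min_times must be >= 2")
  counts <- table(unlist(lapply(sets, function(s) unique(s$genes)),
                         use.names = FALSE))
  sort(names(counts)[counts >= min_times])
}

#' Map a gene set onto a network
#'
#' Partitions a set's members by presence in the network's node set. All
#' downstream set-level measures operate on the `in_network` part only; the
#' dropped count is always carried along.
#'
#' @param s a `gene_set` (or character vector of symbols).
#' @param net a `ppi_network`.
#' @return Object of class `mapped_gene_set` with fields `origin`,
#'   `in_network`, `dropped`.
#' @export
map_to_network <- function(s, net) {
  if (!inherits(s, "gene_set")) s <- gene_set("<character>", s)
  nodes <- network_nodes(net)
  in_net <- intersect(s$genes, nodes)
  dropped <- setdiff(s$genes, nodes)
  if (length(in_net) == 0L) {
    warning("gene set '", s$name, "': no members present in the network")
  }
  structure(list(origin = s$name, in_network = in_net, dropped = dropped),
            class = "mapped_gene_set")
}

#' @export
print.mapped_gene_set <- function(x, ...) {
  cat(sprintf("<mapped_gene_set> %s: %d in network, %d dropped\n",
              x$origin, length(x$in_network), length(x$dropped)))
  invisible(x)
}
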