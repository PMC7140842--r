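# Synthetic networks and planted gene sets: a stated world in which every
# stage of the analysis is testable without downloads, with ground truth
# recorded for parameter-recovery tests.

#' Generate a synthetic network
#'
#' Two generators:
#' \itemize{
#'   \item `planted_partition`: blocks of given sizes with independent
#'     Bernoulli edges — probability `p_in` within a block, `p_out` between
#'     blocks (requires `0 <= p_out <= p_in <= 1`). Emulates the modular
#'     structure module detection is pointed at. The generating block
#'     assignment is recorded in `$truth_partition` so detector error and
#'     measure behavior can be assessed independently.
#'   \item `preferential_attachment`: Barabási–Albert growth. Starts from
#'     `m_attach` unconnected seed nodes; each subsequent node attaches to
#'     `m_attach` distinct existing nodes with probability proportional to
#'     degree (the first newcomer connects to all seeds). Edge count is
#'     exactly `m_attach * (n_nodes - m_attach)`. Emulates the heavy-tailed
#'     degree distribution of real interactomes.
#' }
#'
#' @param generator `"planted_partition"` or `"preferential_attachment"`.
#' @param n_nodes node count (preferential_attachment; for
#'   planted_partition it is implied by `block_sizes`).
#' @param block_sizes integer vector of block sizes (planted_partition).
#' @param p_in,p_out within/between-block edge probabilities.
#' @param m_attach edges added per new node (preferential_attachment).
#' @param seed integer RNG seed; all randomness is local to this call.
#' @return A `ppi_network`; for planted_partition with an extra
#'   `truth_partition` element (named integer vector node -> block).
#' @export
generate_network <- function(generator = c("planted_partition",
                                           "preferential_attachment"),
                             n_nodes = NULL, block_sizes = NULL,
                             p_in = NULL, p_out = NULL, m_attach = 3L,
                             seed = 1L) {
  generator <- match.arg(generator)
  if (generator == "planted_partition") {
    stopifnot(length(block_sizes) >= 1L, all(block_sizes >= 1L))
    if (is.null(p_in) || is.null(p_out) ||
        p_out < 0 || p_in > 1 || p_out > p_in) {
      stop("need 0 <= p_out <= p_in <= 1")
    }
    n <- sum(block_sizes)
    nodes <- sprintf("g%04d", seq_len(n))
    blk <- rep(seq_along(block_sizes), block_sizes)
    ut <- which(upper.tri(matrix(FALSE, n, n)))
    i <- ((ut - 1L) %% n) + 1L
    j <- ((ut - 1L) %/% n) + 1L
    pr <- ifelse(blk[i] == blk[j], p_in, p_out)
    keep <- with_seed(seed, stats::runif(length(pr)) < pr)
    net <- ppi_network(cbind(nodes[i[keep]], nodes[j[keep]]), nodes = nodes,
                       provenance = sprintf(
                         "planted_partition(%s, p_in=%g, p_out=%g, seed=%d)",
                         paste(block_sizes, collapse = "+"), p_in, p_out,
                         as.integer(seed)))
    net$truth_partition <- stats::setNames(blk, nodes)
    net
  } else {
    m <- as.integer(m_attach)
    n <- as.integer(n_nodes)
    if (is.null(n) || n < m + 1L) stop("need n_nodes > m_attach")
    nodes <- sprintf("g%04d", seq_len(n))
    deg <- integer(n)
    from <- integer(m * (n - m))
    to <- integer(m * (n - m))
    k <- 0L
    with_seed(seed, {
      for (v in (m + 1L):n) {
        existing <- seq_len(v - 1L)
        targets <- if (v == m + 1L) {
          existing                      # first newcomer links to all seeds
        } else {
          sample(existing, m, prob = deg[existing])
        }
        idx <- k + seq_along(targets)
        from[idx] <- v
        to[idx] <- targets
        k <- k + length(targets)
        deg[v] <- deg[v] + length(targets)
        deg[targets] <- deg[targets] + 1L
      }
    })
    ppi_network(cbind(nodes[from], nodes[to]), nodes = nodes,
                provenance = sprintf(
                  "preferential_attachment(n=%d, m=%d, seed=%d)",
                  n, m, as.integer(seed)))
  }
}

#' Plant a gene set with controlled topology
#'
#' Sampling modes emulating the behaviors the analysis is meant to detect:
#' \describe{
#'   \item{uniform}{without-replacement uniform sample of network nodes —
#'     the random-background analog.}
#'   \item{module_concentrated}{fraction `rho` (default 0.9) sampled from
#'     the target block(s) of the generating partition, remainder uniform
#'     from the rest — high-GDM, low-IAD sets.}
#'   \item{hub_biased}{sampling probability proportional to
#'     `degree^alpha` (default `alpha = 2`; `alpha = 0` reduces to
#'     uniform) — the high-centrality analog of cancer/metastasis sets.}
#'   \item{compact}{breadth-first ball around a seed node truncated to
#'     `size` (ties within the outermost ring broken at random) — minimal
#'     intra-set distance.}
#' }
#'
#' @param net a `ppi_network`.
#' @param truth_partition named vector node -> block
#'   (module_concentrated); defaults to `net$truth_partition`.
#' @param mode one of `"uniform"`, `"module_concentrated"`,
#'   `"hub_biased"`, `"compact"`.
#' @param size set size.
#' @param params mode-specific list: `blocks` + `rho`
#'   (module_concentrated), `alpha` (hub_biased), `seed_node` (compact).
#' @param seed integer RNG seed.
#' @return Object of class `c("planted_set", "gene_set")` with the usual
#'   `name`/`genes` plus `mode` and `truth` (how the set was built).
#' @export
plant_gene_set <- function(net, truth_partition = NULL,
                           mode = c("uniform", "module_concentrated",
                                    "hub_biased", "compact"),
                           size, params = list(), seed = 1L) {
  mode <- match.arg(mode)
  nodes <- network_nodes(net)
  size <- as.integer(size)
  if (size > length(nodes)) stop("size exceeds available node pool")
  truth_partition <- truth_partition %||% net$truth_partition
  genes <- with_seed(seed, switch(mode,
    uniform = sample(nodes, size),
    module_concentrated = {
      if (is.null(truth_partition)) stop("module_concentrated needs a truth_partition")
      blocks <- params$blocks %||% 1L
      rho <- params$rho %||% 0.9
      pool_in <- names(truth_partition)[truth_partition %in% blocks]
      pool_out <- setdiff(nodes, pool_in)
      k_in <- min(round(rho * size), length(pool_in))
      k_out <- size - k_in
      if (k_out > length(pool_out)) stop("node pool too small")
      c(sample(pool_in, k_in), if (k_out > 0L) sample(pool_out, k_out))
    },
    hub_biased = {
      alpha <- params$alpha %||% 2
      deg <- igraph::degree(net$graph)[nodes]
      w <- as.numeric(deg)^alpha        # alpha = 0 gives uniform weights
      if (sum(w > 0) < size) stop("too few positive-weight nodes")
      sample(nodes, size, prob = w)
    },
    compact = {
      seed_node <- params$seed_node %||% sample(nodes, 1L)
      d <- igraph::distances(net$graph, v = seed_node)[1L, ]
      reachable <- names(d)[is.finite(d)]
      if (length(reachable) < size) stop("reachable pool too small")
      ord <- order(d[reachable], stats::runif(length(reachable)))
      reachable[ord][seq_len(size)]
    }))
  out <- gene_set(params$name %||% paste0("planted_", mode), genes)
  out$mode <- mode
  out$truth <- c(list(size = size, seed = as.integer(seed)), params)
  class(out) <- c("planted_set", class(out))
  out
}

#' Emit a complete miniature study to disk
#'
#' Writes everything the pipeline consumes: a planted-partition network
#' (TSV edge list with per-edge synthetic confidence scores), nine
#' module-concentrated "prognostic" sets plus four contrast sets
#' (hub-biased, uniform, compact) in GMT, a gene universe containing all
#' network nodes plus off-network symbols, a small alias table, an
#' annotation table with planted enriched terms (plus IEA decoys), and a
#' ready-to-run JSON pipeline config. All content is synthetic.
#'
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed.
#' @param b,set_size null-distribution parameters written into the config
#'   (kept small by default so the fixture runs in seconds).
#' @return Named list of file paths plus the generated network (invisibly
#'   reusable by tests).
#' @export
make_fixture_study <- function(dir, seed = 1L, b = 50L, set_size = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- rep(50L, 6L)
  net <- generate_network("planted_partition", block_sizes = blocks,
                          p_in = 0.25, p_out = 0.01, seed = seed)
  nodes <- network_nodes(net)
  el <- network_edges(net)
  paths <- list()

  # network with synthetic confidence scores in [0.4, 1]
  scores <- with_seed(seed + 1L, round(stats::runif(nrow(el), 0.4, 1), 3))
  paths$network <- file.path(dir, "network.tsv")
  writeLines(c("# geneA\tgeneB\tscore",
               paste(el[, 1L], el[, 2L], scores, sep = "\t")),
             paths$network)

  # nine module-concentrated "prognostic" sets + four contrast sets
  sets <- lapply(1:9, function(i) {
    plant_gene_set(net, mode = "module_concentrated", size = set_size,
                   params = list(blocks = ((i - 1L) %% 6L) + 1L, rho = 0.9,
                                 name = sprintf("S%d", i)),
                   seed = seed + 10L + i)
  })
  contrast <- list(
    plant_gene_set(net, mode = "hub_biased", size = set_size,
                   params = list(alpha = 2, name = "CA"), seed = seed + 31L),
    plant_gene_set(net, mode = "hub_biased", size = set_size,
                   params = list(alpha = 1, name = "MA"), seed = seed + 32L),
    plant_gene_set(net, mode = "uniform", size = set_size,
                   params = list(name = "ES"), seed = seed + 33L),
    plant_gene_set(net, mode = "compact", size = set_size,
                   params = list(name = "HK"), seed = seed + 34L))
  all_sets <- c(sets, contrast)
  paths$gene_sets <- file.path(dir, "sets.gmt")
  write_gmt(all_sets, paths$gene_sets, descriptions = "synthetic")

  # universe: all nodes + 10% off-network symbols
  off <- sprintf("x%04d", seq_len(round(length(nodes) * 0.1)))
  paths$universe <- file.path(dir, "universe.txt")
  writeLines(c(nodes, off), paths$universe)

  # alias table mapping a few fake aliases onto real nodes
  ali <- with_seed(seed + 2L, sample(nodes, 5L))
  paths$alias <- file.path(dir, "alias.tsv")
  writeLines(paste(paste0("ALIAS_", ali), ali, sep = "\t"), paths$alias)

  # annotations: one planted term per block (most of the block's genes,
  # sizes within [30, 300]), uniform decoy terms, and IEA records that the
  # loader must drop
  blk <- net$truth_partition
  ann <- do.call(rbind, lapply(1:6, function(bk) {
    members <- names(blk)[blk == bk]
    genes <- with_seed(seed + 40L + bk,
                       sample(members, min(40L, length(members))))
    data.frame(gene = genes, term_id = sprintf("T%04d", bk),
               term_name = sprintf("planted block %d process", bk),
               evidence = "EXP", stringsAsFactors = FALSE)
  }))
  decoys <- do.call(rbind, lapply(7:9, function(tk) {
    genes <- with_seed(seed + 40L + tk, sample(nodes, 35L))
    data.frame(gene = genes, term_id = sprintf("T%04d", tk),
               term_name = sprintf("decoy process %d", tk),
               evidence = "EXP", stringsAsFactors = FALSE)
  }))
  iea <- data.frame(gene = with_seed(seed + 50L, sample(nodes, 40L)),
                    term_id = "T9999", term_name = "electronic decoy",
                    evidence = "IEA", stringsAsFactors = FALSE)
  ann <- rbind(ann, decoys, iea)
  paths$annotations <- file.path(dir, "annotations.tsv")
  writeLines(c("# gene\tterm_id\tterm_name\tevidence",
               paste(ann$gene, ann$term_id, ann$term_name, ann$evidence,
                     sep = "\t")),
             paths$annotations)

  # pipeline config (module min_size 30 matches the retention filter the
  # block sizes were chosen to exercise)
  cfg <- list(network = list(path = paths$network, score_threshold = 0.6,
                             score_column = 3L),
              gene_sets = paths$gene_sets,
              alias_table = paths$alias,
              universe = paths$universe,
              null = list(b = b, set_size = set_size, seed = seed,
                          universe = "network"),
              module_min_size = 30L,
              # induced mode: the fixture blocks are dense enough that
              # member-member edge counts are never degenerate, and induced
              # GDM is the variant sensitive to the planted concentration
              gdm_mode = "induced",
              cc_mode = "node_average",
              enrichment = list(annotations = paths$annotations,
                                min_term = 30L, max_term = 300L,
                                excluded_evidence = list("IEA"),
                                q_threshold = 0.05),
              output_dir = file.path(dir, "out"))
  paths$config <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths$net <- net
  invisible(paths)
}
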