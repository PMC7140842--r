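# End-to-end orchestration from a single declarative config.

#' Run the full gene-set network-topology analysis
#'
#' Stages: load + clean the network (optional score filter); load gene sets
#' (optional alias normalization) and map them; centralities, background
#' means and all-pairs one-tailed group comparisons with FDR; shortest-path
#' matrix, per-set CC and IAD, pairwise IED; module detection with the
#' size-retention filter and per-set GDM; random-set null distributions
#' with permutation and one-tailed KS tests; optional Fisher enrichment of
#' qualifying modules plus pairwise term intersections. Each stage writes a
#' TSV; a JSON manifest records parameters, seeds, versions, dropped-gene
#' counts and stage status. Deterministic given the config seeds: re-running
#' reproduces all TSV payloads byte for byte.
#'
#' Null-test directions follow the questions the measures were built for:
#' IAD, IED and CC are tested "less" (sets more compact/clustered than
#' random), GDM "greater" (sets concentrated within modules).
#'
#' @param config path to a JSON config file, or an equivalent named list.
#'   Fields: `network` (list: `path`, optional `score_threshold`,
#'   `score_column`, `node_file`), `gene_sets` (GMT path), optional
#'   `alias_table`, optional `universe` (one symbol per line; defaults to
#'   network nodes), `null` (list: `b`, `set_size`, `seed`, `universe` =
#'   `"file"` or `"network"`), `module_min_size`, `gdm_mode`, `cc_mode`,
#'   optional `enrichment` (list: `annotations`, `min_term`, `max_term`,
#'   `excluded_evidence`, `q_threshold`), `output_dir`.
#' @param out_dir overrides `config$output_dir`.
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- validate_config(config)
  out <- out_dir %||% cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("netprops")),
                   r_version = R.version.string,
                   parameters = cfg[setdiff(names(cfg), "output_dir")],
                   stages = list())
  res <- list(out_dir = out)
  stage <- function(name, expr) {
    message("[netprops] stage: ", name)
    val <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    val
  }

  net <- stage("network", {
    load_edge_list(cfg$network$path,
                   score_threshold = cfg$network$score_threshold,
                   score_column = cfg$network$score_column %||% 3L,
                   node_file = cfg$network$node_file)
  })
  summ <- summarize_network(net)
  write_tsv(data.frame(key = names(summ), value = unlist(summ)),
            file.path(out, "network_summary.tsv"))

  sets <- stage("gene_sets", {
    s <- parse_gmt(cfg$gene_sets)
    if (!is.null(cfg$alias_table)) {
      s <- suppressMessages(normalize_symbols(s, load_alias_table(cfg$alias_table)))
    }
    s
  })
  mapped <- lapply(sets, function(s) suppressWarnings(map_to_network(s, net)))
  manifest$dropped_genes <- lapply(mapped, function(m) length(m$dropped))

  sp <- stage("shortest_paths", sp_matrix(net))
  cent <- stage("centralities", compute_centralities(net, sp = sp))
  write_tsv(cent, file.path(out, "centralities.tsv"))
  measures <- c("degree", "betweenness", "closeness", "eigenvector")
  bg <- data.frame(measure = measures,
                   background_mean = vapply(measures, function(m)
                     background_mean(cent, m), numeric(1L)))
  write_tsv(bg, file.path(out, "background_means.tsv"))

  comp <- stage("group_comparisons", {
    usable <- Filter(function(m) length(m$in_network) >= 2L, mapped)
    pairs <- if (length(usable) >= 2L) utils::combn(names(usable), 2L) else NULL
    rows <- list()
    if (!is.null(pairs)) {
      for (k in seq_len(ncol(pairs))) {
        for (m in measures) {
          rows[[length(rows) + 1L]] <-
            compare_groups(cent, usable[[pairs[1L, k]]],
                           usable[[pairs[2L, k]]], m, direction = "greater")
        }
      }
    }
    cc <- do.call(rbind, rows)
    if (!is.null(cc)) cc$q <- fdr_adjust(cc$p)
    cc
  })
  if (!is.null(comp)) write_tsv(comp, file.path(out, "group_comparisons.tsv"))

  part <- stage("modules", detect_modules(net, min_size = cfg$module_min_size))
  export_partition(part, file.path(out, "modules.tsv"))

  metrics <- stage("set_metrics", {
    do.call(rbind, lapply(mapped, function(ms) {
      n_in <- length(ms$in_network)
      data.frame(set = ms$origin, n_used = n_in, n_dropped = length(ms$dropped),
                 cc = if (n_in >= 1L)
                   set_clustering_coefficient(net, ms, mode = cfg$cc_mode)
                 else NA_real_,
                 iad = if (n_in >= 2L) intra_set_distance(sp, ms)$iad
                 else NA_real_,
                 gdm = if (n_in >= 1L)
                   gdm(net, part, ms, mode = cfg$gdm_mode)$gdm
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  write_tsv(metrics, file.path(out, "set_metrics.tsv"))

  ied_tab <- stage("ied", {
    usable <- Filter(function(m) length(m$in_network) >= 1L, mapped)
    nms <- names(usable)
    rows <- list()
    if (length(nms) >= 2L) {
      pr <- utils::combn(nms, 2L)
      for (k in seq_len(ncol(pr))) {
        r <- inter_set_distance(sp, usable[[pr[1L, k]]], usable[[pr[2L, k]]])
        rows[[k]] <- data.frame(set_p = r$set_p, set_q = r$set_q,
                                n_p = r$n_p, n_q = r$n_q,
                                mean_p_to_q = r$mean_p_to_q,
                                mean_q_to_p = r$mean_q_to_p, ied = r$ied,
                                stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  if (!is.null(ied_tab)) write_tsv(ied_tab, file.path(out, "ied.tsv"))

  nulls <- stage("null_tests", {
    uni <- if (identical(cfg$null$universe, "network") || is.null(cfg$universe)) {
      network_nodes(net)
    } else {
      readLines(cfg$universe, warn = FALSE)
    }
    rnd <- sample_random_sets(uni, set_size = cfg$null$set_size,
                              b = cfg$null$b, seed = cfg$null$seed)
    ref <- merge_sets(sets, "all_sets_union")
    nd <- list(cc = null_distribution(net, sp, part, rnd, "cc",
                                      cc_mode = cfg$cc_mode),
               iad = null_distribution(net, sp, part, rnd, "iad"),
               ied = null_distribution(net, sp, part, rnd, "ied",
                                       reference_set = ref),
               gdm = null_distribution(net, sp, part, rnd, "gdm",
                                       gdm_mode = cfg$gdm_mode))
    nv <- do.call(rbind, lapply(names(nd), function(m) {
      data.frame(measure = m, replicate = seq_along(nd[[m]]$values),
                 value = nd[[m]]$values, stringsAsFactors = FALSE)
    }))
    write_tsv(nv, file.path(out, "null_values.tsv"))
    direction <- c(cc = "less", iad = "less", ied = "less", gdm = "greater")
    rows <- list()
    for (m in names(nd)) {
      obs <- switch(m,
        cc = stats::setNames(metrics$cc, metrics$set),
        iad = stats::setNames(metrics$iad, metrics$set),
        gdm = stats::setNames(metrics$gdm, metrics$set),
        ied = if (!is.null(ied_tab))
          stats::setNames(ied_tab$ied, paste(ied_tab$set_p, ied_tab$set_q,
                                             sep = "|")) else NULL)
      obs <- obs[!is.na(obs)]
      for (nm in names(obs)) {
        pt <- permutation_p(obs[[nm]], nd[[m]], alternative = direction[[m]])
        rows[[length(rows) + 1L]] <-
          data.frame(set = nm, measure = m, method = "permutation",
                     alternative = direction[[m]], statistic = pt$statistic,
                     p = pt$p, stringsAsFactors = FALSE)
      }
      if (length(obs) >= 1L) {
        kt <- ks_one_sided(unname(obs), nd[[m]]$values,
                           alternative = direction[[m]])
        rows[[length(rows) + 1L]] <-
          data.frame(set = "<all sets>", measure = m, method = "ks_one_sided",
                     alternative = direction[[m]], statistic = kt$statistic,
                     p = kt$p, stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, rows)
    write_tsv(tests, file.path(out, "null_tests.tsv"))
    list(null = nd, tests = tests,
         n_dropped = vapply(nd, `[[`, integer(1L), "n_dropped"))
  })
  manifest$null_dropped <- as.list(nulls$n_dropped)

  if (!is.null(cfg$enrichment)) {
    enr <- stage("enrichment", {
      ec <- cfg$enrichment
      ann <- load_annotations(ec$annotations,
                              min_term = ec$min_term %||% 30L,
                              max_term = ec$max_term %||% 300L,
                              excluded_evidence = unlist(ec$excluded_evidence %||% "IEA"),
                              background = network_nodes(net))
      qual <- modules_with_min_sets(part, mapped, min_sets = 2L)
      per_module <- list()
      for (i in seq_len(nrow(qual))) {
        mod <- qual$module[i]
        genes <- names(part$assignment)[part$assignment == mod]
        r <- fisher_enrichment(genes, ann,
                               q_threshold = ec$q_threshold %||% 0.05)
        per_module[[as.character(mod)]] <- r
        if (nrow(r)) {
          write_tsv(cbind(module = mod, r),
                    file.path(out, sprintf("enrichment_module_%d.tsv", mod)))
        }
      }
      inter <- list()
      mods <- names(per_module)
      if (length(mods) >= 2L) {
        pr <- utils::combn(mods, 2L)
        for (k in seq_len(ncol(pr))) {
          ti <- term_intersection(per_module[[pr[1L, k]]],
                                  per_module[[pr[2L, k]]])
          if (nrow(ti)) {
            inter[[length(inter) + 1L]] <-
              cbind(module_a = pr[1L, k], module_b = pr[2L, k], ti)
          }
        }
      }
      inter <- if (length(inter)) do.call(rbind, inter) else NULL
      if (!is.null(inter)) {
        write_tsv(inter, file.path(out, "module_term_intersection.tsv"))
      }
      list(qualifying_modules = qual, per_module = per_module,
           intersection = inter)
    })
    res$enrichment <- enr
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  res <- c(res, list(network = net, summary = summ, sets = sets,
                     mapped = mapped, centralities = cent,
                     comparisons = comp, partition = part,
                     set_metrics = metrics, ied = ied_tab,
                     null_tests = nulls$tests))
  invisible(res)
}

validate_config <- function(cfg) {
  need <- function(cond, field, msg) {
    if (!cond) stop("config field '", field, "': ", msg, call. = FALSE)
  }
  need(!is.null(cfg$network) && !is.null(cfg$network$path), "network.path",
       "missing")
  need(file.exists(cfg$network$path), "network.path",
       paste0("file not found ('", cfg$network$path, "')"))
  need(!is.null(cfg$gene_sets), "gene_sets", "missing")
  need(file.exists(cfg$gene_sets), "gene_sets",
       paste0("file not found ('", cfg$gene_sets, "')"))
  for (f in c("alias_table", "universe")) {
    if (!is.null(cfg[[f]])) {
      need(file.exists(cfg[[f]]), f,
           paste0("file not found ('", cfg[[f]], "')"))
    }
  }
  cfg$null <- cfg$null %||% list()
  cfg$null$b <- cfg$null$b %||% 1000L
  cfg$null$set_size <- cfg$null$set_size %||% 120L
  cfg$null$seed <- cfg$null$seed %||% 1L
  cfg$null$universe <- cfg$null$universe %||% "file"
  need(cfg$null$b >= 1, "null.b", "must be >= 1")
  need(cfg$null$set_size >= 2, "null.set_size", "must be >= 2")
  cfg$module_min_size <- cfg$module_min_size %||% 30L
  cfg$gdm_mode <- cfg$gdm_mode %||% "incident"
  cfg$cc_mode <- cfg$cc_mode %||% "node_average"
  if (!is.null(cfg$enrichment)) {
    need(!is.null(cfg$enrichment$annotations), "enrichment.annotations",
         "missing")
    need(file.exists(cfg$enrichment$annotations), "enrichment.annotations",
         paste0("file not found ('", cfg$enrichment$annotations, "')"))
  }
  need(!is.null(cfg$output_dir), "output_dir", "missing")
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
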