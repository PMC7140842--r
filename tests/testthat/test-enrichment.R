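make_ann <- function(records, background, ...) {
  annotation_table(records, background = background, ...)
}

ann_df <- function(gene, term, evidence = "EXP") {
  data.frame(gene = gene, term_id = term, term_name = paste("name", term),
             evidence = evidence, stringsAsFactors = FALSE)
}

test_that("annotation filters: IEA first, background restriction, size window", {
  bg <- sprintf("G%03d", 1:400)
  recs <- rbind(ann_df(bg[1:29], "T29"), ann_df(bg[1:30], "T30"),
                ann_df(bg[1:300], "T300"), ann_df(bg[1:301], "T301"))
  ann <- make_ann(recs, bg, min_term = 30, max_term = 300)
  expect_setequal(names(ann$term_sizes), c("T30", "T300"))
  expect_equal(unname(ann$term_sizes[c("T30", "T300")]), c(30L, 300L))

  # IEA records dropped regardless of term size
  recs2 <- rbind(ann_df(bg[1:50], "TOK"),
                 ann_df(bg[1:50], "TIEA", evidence = "IEA"))
  ann2 <- make_ann(recs2, bg)
  expect_equal(names(ann2$term_sizes), "TOK")

  # genes outside the background are ignored in term sizes: 35 in-background
  # plus 10 outside stays within [30, 40] window counted on background only
  recs3 <- ann_df(c(bg[1:35], sprintf("X%02d", 1:10)), "TB")
  ann3 <- make_ann(recs3, bg, min_term = 30, max_term = 40)
  expect_equal(unname(ann3$term_sizes["TB"]), 35L)

  f <- withr::local_tempfile(lines = c("g1\tT1\tname\tEXP", "g2\tT1\tname"))
  expect_error(load_annotations(f, background = bg), "line 2")
})

test_that("Fisher p equals the hypergeometric tail oracle", {
  # the spec's worked numbers: N = 1000, n = 100, K = 30, k = 10
  bg <- sprintf("G%04d", 1:1000)
  term_genes <- bg[1:30]
  query <- c(bg[1:10], bg[31:120])  # overlap 10, size 100
  ann <- make_ann(ann_df(term_genes, "T1"), bg)
  res <- attr(fisher_enrichment(query, ann, q_threshold = 1), "all")
  expect_equal(res$k, 10L)
  expect_equal(res$p, oracle_hyper_tail(10, 30, 1000, 100))
  # and the classical fisher.test cross-check
  ft <- fisher.test(matrix(c(10, 90, 20, 880), 2), alternative = "greater")
  expect_equal(res$p, ft$p.value, tolerance = 1e-9)

  # k = 0: no over-representation, p >= 0.5, never reported
  bg2 <- sprintf("G%04d", 1:200)
  ann2 <- make_ann(ann_df(bg2[1:40], "T1"), bg2, min_term = 30)
  none <- fisher_enrichment(bg2[41:80], ann2)
  expect_equal(nrow(none), 0L)
  expect_gte(attr(none, "all")$p, 0.5)

  # query = whole background: k = K for every term, p = 1
  degen <- attr(fisher_enrichment(bg2, ann2, q_threshold = 1), "all")
  expect_equal(degen$k, degen$K)
  expect_equal(degen$p, 1)
})

test_that("enrichment q-values are monotone and dropping a gene raises p", {
  set.seed(14)
  bg <- sprintf("G%03d", 1:300)
  recs <- do.call(rbind, lapply(1:5, function(i) {
    ann_df(sample(bg, 40), paste0("T", i))
  }))
  ann <- make_ann(recs, bg)
  q <- sample(bg, 60)
  res <- attr(fisher_enrichment(q, ann, q_threshold = 1), "all")
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  expect_true(all(res$q >= res$p))
  # removing an annotated query gene never decreases p for its term
  t1_genes <- unique(ann$records$gene[ann$records$term_id == "T1"])
  hit <- intersect(q, t1_genes)
  if (length(hit)) {
    res2 <- attr(fisher_enrichment(setdiff(q, hit[1]), ann,
                                   q_threshold = 1), "all")
    expect_gte(res2$p[res2$term_id == "T1"], res$p[res$term_id == "T1"])
  }
})

test_that("modules_with_min_sets reports exactly the qualifying modules", {
  net <- generate_network("planted_partition", block_sizes = c(20, 20, 20),
                          p_in = 0.5, p_out = 0.01, seed = 6)
  part <- detect_modules(net, min_size = 10)
  blk <- net$truth_partition
  b1 <- names(blk)[blk == 1]
  s1 <- map_to_network(gene_set("S1", b1[1:8]), net)
  s3 <- map_to_network(gene_set("S3", b1[9:16]), net)
  s2 <- map_to_network(gene_set("S2", names(blk)[blk == 2][1:8]), net)
  got <- modules_with_min_sets(part, list(s1, s2, s3), min_sets = 2)
  expect_equal(nrow(got), 1L)
  expect_setequal(got$sets[[1]], c("S1", "S3"))
  # min_genes_per_set raises the bar
  none <- modules_with_min_sets(part, list(s1, s2, s3), min_sets = 2,
                                min_genes_per_set = 9)
  expect_equal(nrow(none), 0L)
})

test_that("term_intersection keeps common terms with the larger p", {
  a <- data.frame(term_id = c("T1", "T2", "T3"),
                  term_name = paste("name", c("T1", "T2", "T3")),
                  q = c(0.001, 0.01, 0.02), stringsAsFactors = FALSE)
  b <- data.frame(term_id = c("T2", "T3", "T4"),
                  term_name = paste("name", c("T2", "T3", "T4")),
                  q = c(0.04, 0.005, 0.01), stringsAsFactors = FALSE)
  ti <- term_intersection(a, b)
  expect_setequal(ti$term_id, c("T2", "T3"))
  expect_equal(ti$combined_p[ti$term_id == "T2"], 0.04)
  expect_equal(ti$combined_p[ti$term_id == "T3"], 0.02)
  expect_true(!is.unsorted(ti$combined_p))
  disjoint <- term_intersection(a, b[b$term_id == "T4", ])
  expect_equal(nrow(disjoint), 0L)
})
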