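two_cliques_bridge <- function() {
  c1 <- t(utils::combn(paste0("a", 1:5), 2))
  c2 <- t(utils::combn(paste0("b", 1:5), 2))
  ppi_network(rbind(c1, c2, c("a1", "b1")))
}

test_that("greedy detector separates two bridged cliques", {
  net <- two_cliques_bridge()
  part <- detect_modules(net, min_size = 3)
  a_mods <- unique(part$assignment[paste0("a", 1:5)])
  b_mods <- unique(part$assignment[paste0("b", 1:5)])
  expect_length(a_mods, 1)
  expect_length(b_mods, 1)
  expect_false(a_mods == b_mods)
  expect_setequal(part$retained, c(a_mods, b_mods))
  # the 2-clique split maximizes Q over natural contenders
  all_one <- setNames(rep(1L, n_nodes(net)), network_nodes(net))
  singletons <- setNames(seq_len(n_nodes(net)), network_nodes(net))
  expect_gt(part$modularity, partition_modularity(net, all_one))
  expect_gt(part$modularity, partition_modularity(net, singletons))
})

test_that("a clique collapses to one module; the size filter retains >= min", {
  clique <- ppi_network(t(utils::combn(paste0("n", 1:6), 2)))
  part <- detect_modules(clique, min_size = 3)
  expect_length(unique(part$assignment), 1)
  expect_equal(part$retained, 1L)
  # sizes {40, 25} with min_size 30 -> only the 40-block retained
  net <- generate_network("planted_partition", block_sizes = c(40, 25),
                          p_in = 0.5, p_out = 0, seed = 2)
  p2 <- detect_modules(net, min_size = 30)
  retained_sizes <- p2$sizes[p2$retained]
  expect_true(all(retained_sizes >= 30))
  expect_equal(sum(p2$sizes[p2$retained]), 40)
  expect_equal(sort(p2$sizes, decreasing = TRUE)[1:2], c(40, 25))
})

test_that("partition invariants: coverage, Q recomputation, determinism", {
  g <- rand_graph(40, 0.12, seed = 50)
  part <- detect_modules(g$net, min_size = 5)
  expect_setequal(names(part$assignment), network_nodes(g$net))
  # Q >= the all-singletons baseline
  singles <- setNames(seq_len(40), network_nodes(g$net))
  expect_gte(part$modularity, partition_modularity(g$net, singles))
  # matches an independent Q recomputation (definition oracle and igraph)
  expect_equal(part$modularity,
               oracle_modularity(g$edges, part$assignment), tolerance = 1e-12)
  ig_q <- igraph::modularity(g$net$graph,
                             part$assignment[igraph::V(g$net$graph)$name])
  expect_equal(part$modularity, ig_q, tolerance = 1e-12)
  # byte-determinism across calls
  expect_identical(part$assignment, detect_modules(g$net, min_size = 5)$assignment)
  expect_error(detect_modules(ppi_network(matrix(character(0), ncol = 2))),
               "empty network")
})

test_that("import/export partition round-trips and validates coverage", {
  g <- rand_graph(20, 0.2, seed = 8)
  part <- detect_modules(g$net, min_size = 4)
  f <- withr::local_tempfile()
  export_partition(part, f)
  back <- import_partition(f, g$net, min_size = 4)
  expect_identical(back$assignment, part$assignment)
  expect_identical(back$retained, part$retained)
  expect_equal(back$modularity, part$modularity)
  short <- withr::local_tempfile(lines = "n01\t1")
  expect_error(import_partition(short, g$net), "does not cover")
})

test_that("GDM arithmetic in both modes matches the spec examples", {
  # modules M1 = {a, b, c}, M2 = {d, e}; set {a}; edges a-b, a-d
  net <- ppi_network(cbind(c("a", "a", "b", "d"), c("b", "d", "c", "e")))
  part <- import_partition(
    withr::local_tempfile(lines = c("a\t1", "b\t1", "c\t1", "d\t2", "e\t2")),
    net, min_size = 2)
  r <- gdm(net, part, "a", mode = "incident")
  expect_equal(r$e_intra, 1L)
  expect_equal(r$e_inter, 1L)
  expect_equal(r$gdm, 0.5)
  # induced mode: w-x same module, y-z different modules
  net2 <- ppi_network(cbind(c("w", "y"), c("x", "z")))
  part2 <- import_partition(
    withr::local_tempfile(lines = c("w\t1", "x\t1", "y\t1", "z\t2")),
    net2, min_size = 1)
  r2 <- gdm(net2, part2, c("w", "x", "y", "z"), mode = "induced")
  expect_equal(r2$e_intra, 1L)
  expect_equal(r2$e_inter, 1L)
  expect_equal(r2$gdm, 0.5)
  # all edges within one retained module -> GDM = 1
  r3 <- gdm(net2, part2, c("w", "x"), mode = "induced")
  expect_equal(r3$gdm, 1)
  # no qualifying edge -> undefined, NA not 0
  iso <- ppi_network(cbind("a", "b"), nodes = c("a", "b", "z"))
  p_iso <- import_partition(
    withr::local_tempfile(lines = c("a\t1", "b\t1", "z\t2")), iso,
    min_size = 2)
  r4 <- gdm(iso, p_iso, "z")
  expect_true(r4$undefined)
  expect_true(is.na(r4$gdm))
})

test_that("GDM is in [0,1], label-permutation-invariant, equals the oracle", {
  for (seed in 1:5) {
    g <- rand_graph(25, 0.15, seed = 500 + seed)
    part <- detect_modules(g$net, min_size = 4)
    set.seed(seed)
    s <- sample(g$nodes, 8)
    for (mode in c("incident", "induced")) {
      r <- gdm(g$net, part, s, mode = mode)
      orc <- oracle_gdm(g$edges, part$assignment, part$retained, s, mode)
      expect_equal(r$e_intra, orc$e_intra)
      expect_equal(r$e_inter, orc$e_inter)
      expect_equal(r$gdm, orc$gdm)
      if (!r$undefined) expect_true(r$gdm >= 0 && r$gdm <= 1)
    }
    # permuting module labels leaves GDM unchanged
    ids <- sort(unique(part$assignment))
    perm <- setNames(sample(ids), ids)
    shuffled <- part
    shuffled$assignment <- setNames(perm[as.character(part$assignment)],
                                    names(part$assignment))
    shuffled$retained <- unname(perm[as.character(part$retained)])
    expect_equal(gdm(g$net, shuffled, s)$gdm, gdm(g$net, part, s)$gdm)
  }
})

test_that("module-concentrated sets score higher GDM than uniform sets", {
  # lighter cousin of the acceptance parameter-recovery check
  net <- generate_network("planted_partition", block_sizes = rep(30, 3),
                          p_in = 0.3, p_out = 0.02, seed = 13)
  part <- detect_modules(net, min_size = 20)
  planted <- vapply(1:20, function(i) {
    s <- plant_gene_set(net, mode = "module_concentrated", size = 12,
                        params = list(blocks = 1, rho = 0.9), seed = i)
    gdm(net, part, map_to_network(s, net), mode = "induced")$gdm
  }, numeric(1))
  unif <- vapply(1:50, function(i) {
    s <- plant_gene_set(net, mode = "uniform", size = 12, seed = 1000 + i)
    gdm(net, part, map_to_network(s, net), mode = "induced")$gdm
  }, numeric(1))
  expect_gt(median(planted, na.rm = TRUE), median(unif, na.rm = TRUE))
})
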