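test_that("planted partition degenerates correctly at the edges", {
  # p_in = 1, p_out = 0: disjoint cliques
  net <- generate_network("planted_partition", block_sizes = c(5, 5),
                          p_in = 1, p_out = 0, seed = 1)
  expect_equal(n_edges(net), 2 * choose(5, 2))
  sp <- igraph::components(net$graph)
  expect_equal(sp$no, 2)
  expect_error(generate_network("planted_partition", block_sizes = c(5, 5),
                                p_in = 0.1, p_out = 0.5), "p_out <= p_in")
})

test_that("p_in = p_out reduces to Erdos-Renyi density within 3 SE", {
  p <- 0.1
  n <- 80
  npairs <- choose(n, 2)
  counts <- vapply(1:10, function(seed) {
    n_edges(generate_network("planted_partition",
                             block_sizes = c(40, 40), p_in = p, p_out = p,
                             seed = seed))
  }, integer(1))
  se <- sqrt(p * (1 - p) / (npairs * 10))
  expect_lt(abs(mean(counts) / npairs - p), 3 * se)
})

test_that("preferential attachment bookkeeping is exact", {
  net <- generate_network("preferential_attachment", n_nodes = 2000,
                          m_attach = 3, seed = 2)
  expect_equal(n_edges(net), 3 * (2000 - 3))
  expect_equal(n_nodes(net), 2000L)
  # heavy upper tail: max degree far above the median
  deg <- igraph::degree(net$graph)
  expect_gt(max(deg), 10 * median(deg))
  # determinism
  net2 <- generate_network("preferential_attachment", n_nodes = 2000,
                           m_attach = 3, seed = 2)
  expect_identical(network_edges(net), network_edges(net2))
})

test_that("module_concentrated planting respects rho and the target block", {
  net <- generate_network("planted_partition", block_sizes = c(30, 30),
                          p_in = 0.3, p_out = 0.02, seed = 3)
  s <- plant_gene_set(net, mode = "module_concentrated", size = 20,
                      params = list(blocks = 1, rho = 1), seed = 4)
  blk <- net$truth_partition
  expect_true(all(blk[s$genes] == 1))
  half <- plant_gene_set(net, mode = "module_concentrated", size = 20,
                         params = list(blocks = 1, rho = 0.5), seed = 4)
  expect_equal(sum(blk[half$genes] == 1), 10)
})

test_that("hub_biased with alpha = 0 is uniform; alpha = 2 prefers hubs", {
  net <- generate_network("preferential_attachment", n_nodes = 300,
                          m_attach = 2, seed = 5)
  deg <- igraph::degree(net$graph)
  mean_deg_of <- function(alpha, seeds) {
    vapply(seeds, function(sd) {
      s <- plant_gene_set(net, mode = "hub_biased", size = 30,
                          params = list(alpha = alpha), seed = sd)
      mean(deg[s$genes])
    }, numeric(1))
  }
  unif <- mean_deg_of(0, 1:30)
  hubs <- mean_deg_of(2, 1:30)
  expect_gt(mean(hubs), mean(unif))
  # alpha = 0 should hover around the network mean degree
  expect_lt(abs(mean(unif) - mean(deg)), 3 * sd(unif) / sqrt(30))
})

test_that("compact planting takes the BFS ball and shrinks IAD", {
  path5 <- ppi_network(cbind(letters[1:4], letters[2:5]))
  s <- plant_gene_set(path5, mode = "compact", size = 3,
                      params = list(seed_node = "c"), seed = 1)
  expect_setequal(s$genes, c("b", "c", "d"))
  sp <- sp_matrix(path5)
  # exhaustive check: the ball is the IAD-minimal 3-set containing c
  all3 <- utils::combn(letters[1:5], 3, simplify = FALSE)
  with_c <- Filter(function(x) "c" %in% x, all3)
  iads <- vapply(with_c, function(x) intra_set_distance(sp, x)$iad,
                 numeric(1))
  expect_equal(intra_set_distance(sp, s$genes)$iad, min(iads))
  # and strictly below the uniform expectation over all 3-sets
  expect_lt(intra_set_distance(sp, s$genes)$iad,
            mean(vapply(all3, function(x) intra_set_distance(sp, x)$iad,
                        numeric(1))))
  expect_error(plant_gene_set(path5, mode = "compact", size = 9,
                              params = list(seed_node = "c")),
               "too small|exceeds")
  # unreachable nodes never enter the ball
  split <- ppi_network(cbind(c("a", "c"), c("b", "d")))
  expect_error(plant_gene_set(split, mode = "compact", size = 3,
                              params = list(seed_node = "a")), "too small")
})

test_that("the fixture study is complete and internally consistent", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_study(dir, seed = 11, b = 10, set_size = 25)
  expect_true(all(file.exists(unlist(fx[c("network", "gene_sets",
                                          "universe", "alias",
                                          "annotations", "config")]))))
  sets <- parse_gmt(fx$gene_sets)
  expect_length(sets, 13)           # 9 planted PGS + 4 contrast sets
  expect_setequal(names(sets)[10:13], c("CA", "MA", "ES", "HK"))
  net <- load_edge_list(fx$network, score_threshold = 0.6)
  expect_gt(n_edges(net), 0)
  # IEA decoy term must vanish under the loader's filters
  ann <- load_annotations(fx$annotations, background = network_nodes(net))
  expect_false("T9999" %in% names(ann$term_sizes))
})
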