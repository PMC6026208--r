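test_that("a single-connector path and a 4-cycle are analysed exactly", {
  g <- igraph::make_graph(~ a - x, x - b)
  res <- connector_analysis(g, c("a", "b"))
  expect_equal(res$connectors, "x")
  expect_equal(res$pairs$length, 2L)
  expect_equal(res$pairs$n_geodesics, 1)
  expect_true(all(res$edge_criticality$c_e == 1))
  # 4-cycle with opposite seeds: two geodesics, both off-seed nodes connect
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- c("a", "b", "c", "d")
  res2 <- connector_analysis(ring, c("a", "c"))
  expect_setequal(res2$connectors, c("b", "d"))
  expect_equal(res2$pairs$n_geodesics, 2)
  expect_true(all(res2$edge_criticality$c_e == 1))
  # adjacent seeds contribute no connectors
  res3 <- connector_analysis(g, c("a", "x"))
  expect_length(res3$connectors, 0)
})

test_that("unmapped seeds are reported and too few mapped seeds rejected", {
  g <- igraph::make_graph(~ a - x, x - b)
  res <- connector_analysis(g, c("a", "b", "zz"))
  expect_equal(res$seeds_unmapped, "zz")
  expect_error(connector_analysis(g, c("a", "qq")), "fewer than 2")
})

test_that("connectors and edge counts equal the exhaustive geodesic oracle", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    g <- random_connected_graph(n, runif(1, 0.12, 0.3))
    seeds <- sample(igraph::V(g)$name, sample(3:5, 1))
    got <- connector_analysis(g, seeds)
    exp <- oracle_connectors(g, seeds)
    expect_identical(got$connectors, exp$connectors)
    got_ce <- keyed_criticality(got)
    expect_equal(got_ce[sort(names(got_ce))],
                 exp$edge_counts[sort(names(exp$edge_counts))])
    expect_equal(got$pairs$n_geodesics, exp$pairs$n_geodesics)
  }
})

test_that("edge criticality sums to path length times geodesic count", {
  set.seed(31)
  g <- random_connected_graph(25, 0.18)
  seeds <- sample(igraph::V(g)$name, 4)
  res <- connector_analysis(g, seeds)
  expect_equal(sum(res$edge_criticality$c_e),
               sum(res$pairs$length * res$pairs$n_geodesics))
})

test_that("the analysis is invariant to node relabeling", {
  set.seed(13)
  g <- random_connected_graph(20, 0.2)
  seeds <- sample(igraph::V(g)$name, 3)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  res1 <- connector_analysis(g, seeds)
  res2 <- connector_analysis(g2, seeds)
  expect_identical(res1$connectors, res2$connectors)
  expect_equal(sort(keyed_criticality(res1)), sort(keyed_criticality(res2)))
})

test_that("deleting a non-geodesic edge leaves connectors unchanged", {
  set.seed(41)
  g <- random_connected_graph(22, 0.22)
  seeds <- sample(igraph::V(g)$name, 4)
  res <- connector_analysis(g, seeds)
  idle <- which(res$edge_criticality$c_e == 0)
  if (length(idle)) {
    g2 <- igraph::delete_edges(g, idle[1])
    if (igraph::is_connected(g2)) {
      res2 <- connector_analysis(g2, seeds)
      expect_identical(res2$connectors, res$connectors)
    }
  }
  expect_true(all(res$edge_criticality$c_e >= 0))
})

test_that("weight cutoff removes weak edges before path finding", {
  el <- data.frame(gene1 = c("a", "a"), gene2 = c("b", "c"),
                   weight = c(0.9, 0.2))
  g <- igraph::graph_from_data_frame(el[, 1:2], directed = FALSE)
  igraph::E(g)$weight <- el$weight
  full <- connector_analysis(g, c("b", "c"))
  expect_equal(full$pairs$length, 2L)
  cut <- connector_analysis(g, c("b", "c"), weight_cutoff = 0.5)
  expect_false(cut$pairs$connected)
})

test_that("connector enrichment reproduces the hypergeometric point mass", {
  # 5 connectors, all annotated; 15 more background nodes, none annotated:
  # one-sided Fisher p = 1 / choose(20, 5)
  res <- structure(list(connectors = sprintf("c%d", 1:5),
                        seeds_mapped = c("s1", "s2"),
                        graph = igraph::make_full_graph(2)),
                   class = "connector_result")
  p <- enrich_connectors(res, annotation = sprintf("c%d", 1:5),
                         background = c(sprintf("c%d", 1:5),
                                        sprintf("b%d", 1:15)))$p
  expect_equal(p, 1 / choose(20, 5), tolerance = 1e-4)
  # equal annotation fractions: no enrichment signal
  res2 <- structure(list(connectors = sprintf("c%d", 1:40),
                         seeds_mapped = "s1",
                         graph = igraph::make_full_graph(2)),
                    class = "connector_result")
  p2 <- enrich_connectors(res2,
                          annotation = c(sprintf("c%d", 1:10),
                                         sprintf("b%d", 1:25)),
                          background = c(sprintf("c%d", 1:40),
                                         sprintf("b%d", 1:100)))$p
  expect_gt(p2, 0.05)
  # zero annotated anywhere
  res3 <- structure(list(connectors = c("c1", "c2"), seeds_mapped = "s1",
                         graph = igraph::make_full_graph(2)),
                    class = "connector_result")
  e3 <- enrich_connectors(res3, annotation = character(0),
                          background = c("c1", "c2", "b1", "b2"))
  expect_equal(e3$p, 1)
  expect_true(e3$or_undefined)
})

test_that("random seed controls are seeded and null-calibrated", {
  net <- generate_network(120, list(type = "erdos_renyi", p = 0.06),
                          n_seeds = 5, annotation_fraction = 0.2, seed = 50)
  ctrl <- random_seed_control(net$graph, igraph::V(net$graph)$name, k = 5,
                              n_iter = 40, annotation = net$annotation,
                              seed = 60)
  ctrl2 <- random_seed_control(net$graph, igraph::V(net$graph)$name, k = 5,
                               n_iter = 40, annotation = net$annotation,
                               seed = 60)
  expect_identical(ctrl$results, ctrl2$results)
  # annotation placed uniformly: median odds ratio near 1
  expect_lt(abs(ctrl$or_quantiles[[2]] - 1), 0.75)
  # degenerate pool: point mass at the original result
  res <- connector_analysis(net$graph, net$seeds)
  enr <- enrich_connectors(res, net$annotation)
  pm <- random_seed_control(net$graph, net$seeds, k = length(net$seeds),
                            n_iter = 5, annotation = net$annotation,
                            seed = 61)
  expect_true(all(pm$results$p == enr$p))
})

test_that("graph export writes attributes that survive re-import", {
  g <- igraph::make_graph(~ a - x, x - b)
  igraph::E(g)$weight <- c(0.5, 0.8)
  res <- connector_analysis(g, c("a", "b"))
  prefix <- tempfile("graph")
  out <- export_graph(res, prefix, annotation = "x")
  expect_equal(sort(igraph::V(out)$role), sort(c("seed", "connector",
                                                 "seed")))
  expect_equal(igraph::V(out)$degree,
               unname(igraph::degree(res$graph)))
  back <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(sort(igraph::V(back)$name), c("a", "b", "x"))
  expect_equal(sort(igraph::V(back)$role), sort(igraph::V(out)$role))
  expect_equal(igraph::E(back)$c_e, res$edge_criticality$c_e)
  nodes_tab <- read_tsv(paste0(prefix, "_nodes.tsv"))
  expect_equal(nrow(nodes_tab), 3L)
  expect_true(nodes_tab$annotated[nodes_tab$node == "x"])
  unlink(paste0(prefix, c(".graphml", "_nodes.tsv", "_edges.tsv")))
})
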