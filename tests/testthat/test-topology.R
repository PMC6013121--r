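test_that("degree distribution matches hand counts and sums to one", {
  expect_equal(degree_distribution_curve(graph_k(3))$y, 1)
  star <- degree_distribution_curve(graph_star(4))
  expect_equal(star$k, c(1L, 4L))
  expect_equal(star$y, c(0.8, 0.2))
  p3 <- degree_distribution_curve(graph_path(3))
  expect_equal(p3$y, c(2 / 3, 1 / 3))
  expect_error(degree_distribution_curve(igraph::make_empty_graph(0, FALSE)),
               "empty")
  for (g in list(graph_two_k5(), graph_paw(), planted_fkr_fixture()$network)) {
    expect_equal(sum(degree_distribution_curve(g)$y), 1)
  }
})

test_that("clustering per node and per degree class follows 2e/k(k-1)", {
  k3 <- suppressMessages(clustering_by_degree(graph_k(3)))
  expect_equal(k3$curve$y, 1)
  star <- suppressMessages(clustering_by_degree(graph_star(4)))
  expect_equal(star$nodes$clustering[star$nodes$gene == "HUB"], 0)
  paw <- suppressMessages(clustering_by_degree(graph_paw()))
  expect_equal(paw$nodes$clustering[paw$nodes$gene == "a"], 1 / 3)
  expect_true(all(paw$curve$y >= 0 & paw$curve$y <= 1))
  # degree-1 pendant excluded
  expect_false("d" %in% paw$nodes$gene)
})

test_that("neighbourhood connectivity averages neighbour degrees by class", {
  star <- neighborhood_connectivity(graph_star(4))
  expect_equal(star$y[star$k == 1], 4)
  expect_equal(star$y[star$k == 4], 1)
  expect_equal(neighborhood_connectivity(graph_k(3))$y, 2)
  p4 <- neighborhood_connectivity(graph_path(4))
  expect_equal(p4$y[p4$k == 1], 2)
  expect_equal(p4$y[p4$k == 2], 1.5)
})

test_that("betweenness and closeness reproduce hand values on small graphs", {
  expect_equal(unname(betweenness_centrality(graph_star(4))["HUB"]), 1)
  expect_true(all(betweenness_centrality(graph_k(3)) == 0))
  p3 <- betweenness_centrality(graph_path(3))
  expect_equal(unname(p3[c("A", "B", "C")]), c(0, 1, 0))

  expect_true(all(closeness_centrality(graph_k(3)) == 1))
  c3 <- closeness_centrality(graph_path(3))
  expect_equal(unname(c3["B"]), 1)
  expect_equal(unname(c3["A"]), 2 / 3)
  # per-component convention: two disjoint edges are all maximally close
  g2 <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("C", "D")),
                                    directed = FALSE)
  expect_true(all(closeness_centrality(g2) == 1))
})

test_that("centralities match brute-force enumeration on random graphs", {
  set.seed(401)
  for (rep in 1:25) {
    g <- random_connected_graph(sample(4:7, 1))
    expect_equal(betweenness_centrality(g), oracle_betweenness(g),
                 tolerance = 1e-9)
    expect_equal(closeness_centrality(g), oracle_closeness(g),
                 tolerance = 1e-9)
    ev <- eigenvector_centrality(g)
    expect_equal(as.numeric(ev), as.numeric(oracle_eigenvector(g)),
                 tolerance = 1e-8)
  }
})

test_that("eigenvector centrality is a unit-norm fixed point of A", {
  for (g in list(graph_k(3), graph_star(4), graph_path(3), graph_two_k5())) {
    ev <- eigenvector_centrality(g)
    lam <- attr(ev, "lambda")
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    expect_lt(max(abs(A %*% as.numeric(ev) - lam * as.numeric(ev))), 1e-8)
    expect_equal(sum(ev^2), 1, tolerance = 1e-12)
    expect_true(all(ev >= 0))
  }
  # closed forms: star lambda = 2 with centre/leaf ratio 2; path-of-3 ~ (1, sqrt 2, 1)
  evs <- eigenvector_centrality(graph_star(4))
  expect_equal(attr(evs, "lambda"), 2, tolerance = 1e-9)
  expect_equal(unname(evs["HUB"] / evs["L1"]), 2, tolerance = 1e-8)
  evp <- eigenvector_centrality(graph_path(3))
  expect_equal(attr(evp, "lambda"), sqrt(2), tolerance = 1e-9)
  expect_equal(unname(evp["B"] / evp["A"]), sqrt(2), tolerance = 1e-8)
})

test_that("nodes outside the largest component get zero eigenvector score", {
  g <- igraph::add_vertices(graph_k(4), 2, name = c("X1", "X2"))
  g <- igraph::add_edges(g, c("X1", "X2"))
  ev <- suppressMessages(eigenvector_centrality(g))
  expect_true(all(ev[c("X1", "X2")] == 0))
  expect_true(all(ev[paste0("K", 1:4)] > 0))
})

test_that("metric-vs-degree aggregation is the per-class arithmetic mean", {
  star <- graph_star(4)
  const <- stats::setNames(rep(3.5, 5), igraph::V(star)$name)
  expect_equal(metric_vs_degree(const, star)$y, c(3.5, 3.5))
  bc <- metric_vs_degree(betweenness_centrality(star), star)
  expect_equal(bc$y[bc$k == 1], 0)
  expect_equal(bc$y[bc$k == 4], 1)
  deg <- igraph::degree(star)
  idc <- metric_vs_degree(deg, star)
  expect_equal(idc$y, as.numeric(idc$k))
  expect_error(metric_vs_degree(const[-1], star), "cover every node")
})
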