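test_that("LEV separates planted cliques and leaves indivisible graphs whole", {
  part <- leading_eigenvector_partition(graph_two_k5())
  expect_equal(length(unique(part)), 2)
  expect_true(same_partition(part, stats::setNames(rep(1:2, each = 5),
                                                   paste0("N", 1:10))))
  expect_equal(length(unique(leading_eigenvector_partition(graph_k(4)))), 1)
  # disconnected input: components pre-split
  tt <- igraph::disjoint_union(igraph::make_full_graph(3),
                               igraph::make_full_graph(3))
  igraph::V(tt)$name <- paste0("T", 1:6)
  expect_equal(length(unique(leading_eigenvector_partition(tt))), 2)
})

test_that("modularity matches hand values and the brute-force formula", {
  k3 <- graph_k(3)
  expect_equal(modularity_q(k3, stats::setNames(rep(1, 3), paste0("K", 1:3))), 0)
  expect_equal(modularity_q(k3, stats::setNames(1:3, paste0("K", 1:3))), -1 / 3)
  tt <- igraph::disjoint_union(igraph::make_full_graph(3),
                               igraph::make_full_graph(3))
  igraph::V(tt)$name <- paste0("T", 1:6)
  expect_equal(modularity_q(tt, stats::setNames(rep(1:2, each = 3),
                                                paste0("T", 1:6))), 0.5)
  expect_error(modularity_q(k3, c(K1 = 1, K2 = 1)), "cover every node")
  set.seed(77)
  for (rep in 1:15) {
    g <- random_connected_graph(sample(5:8, 1))
    memb <- stats::setNames(sample(1:3, igraph::vcount(g), replace = TRUE),
                            igraph::V(g)$name)
    expect_equal(modularity_q(g, memb), oracle_modularity(g, memb),
                 tolerance = 1e-12)
  }
})

test_that("LEV tracks the exhaustive bipartition optimum on small graphs", {
  # structured cases: exact agreement
  two <- graph_two_k5()
  best <- oracle_best_bipartition(two)
  expect_true(best$unique && best$q > 0)
  expect_true(same_partition(
    leading_eigenvector_partition(two),
    stats::setNames(best$membership, igraph::V(two)$name)))
  expect_true(oracle_best_bipartition(graph_k(4))$q <= 1e-12)

  # random cases: spectral bisection without fine-tuning occasionally misses
  # the optimum, so require a high agreement rate, not perfection
  set.seed(99)
  eligible <- 0
  agree <- 0
  for (rep in 1:40) {
    g <- random_connected_graph(sample(5:8, 1))
    lev <- leading_eigenvector_partition(g)
    bb <- oracle_best_bipartition(g)
    if (bb$q > 1e-12 && bb$unique && length(unique(lev)) == 2) {
      eligible <- eligible + 1
      if (same_partition(lev, stats::setNames(bb$membership,
                                              igraph::V(g)$name))) {
        agree <- agree + 1
      }
    }
  }
  expect_gte(eligible, 10)
  expect_gte(agree / eligible, 0.9)
})

test_that("module tree recursion terminates at motifs and non-qualifying modules", {
  # K3 input: a single motif record, no recursion
  tr <- build_module_tree(graph_k(3))
  expect_equal(nrow(tr$records), 1)
  expect_true(tr$records$is_motif)
  expect_equal(tr$max_level, 0)

  # triangle-free path: level 0 does not qualify, no children
  trp <- build_module_tree(graph_path(6))
  expect_false(trp$records$qualifies[1])
  expect_equal(trp$max_level, 0)

  # two K5 + bridge: level 1 = the two cliques, each indivisible but qualifying
  tr2 <- build_module_tree(graph_two_k5())
  lvl1 <- tr2$records[tr2$records$level == 1, ]
  expect_equal(nrow(lvl1), 2)
  expect_true(all(lvl1$n_nodes == 5 & lvl1$n_edges == 10 & lvl1$qualifies))
  expect_equal(tr2$max_level, 1)
})

test_that("children partition their parent at every level", {
  for (net in list(graph_two_k5(), planted_fkr_fixture()$network,
                   generate_hierarchical(4, 2))) {
    tr <- build_module_tree(net)
    rec <- tr$records
    for (pid in rec$id[rec$n_children > 0]) {
      kids <- rec$id[!is.na(rec$parent) & rec$parent == pid]
      kid_members <- unlist(tr$members[kids])
      expect_setequal(kid_members, tr$members[[pid]])
      expect_equal(length(kid_members), length(unique(kid_members)))
      expect_true(all(rec$level[match(kids, rec$id)] ==
                        rec$level[rec$id == pid] + 1))
    }
    # motifs qualify by definition
    expect_true(all(!rec$is_motif | rec$qualifies))
  }
})

test_that("hub trajectories report in-module degree and dense rank per level", {
  tr3 <- build_module_tree(graph_k(3))
  t3 <- hub_trajectory(tr3, "K1")
  expect_equal(nrow(t3), 1)
  expect_equal(t3$degree, 2)
  expect_equal(t3$rank, 1)

  tr <- build_module_tree(graph_two_k5())
  tb <- hub_trajectory(tr, "N1")           # bridge endpoint
  expect_equal(tb$degree[tb$level == 0], 5)
  expect_equal(tb$degree[tb$level == 1], 4)
  expect_error(hub_trajectory(tr, "NOPE"), "not in the network")

  # induced subgraphs only lose edges: degree non-increasing along any branch
  trf <- build_module_tree(planted_fkr_fixture()$network)
  for (g in c("A1", "B1", "C1", "D1")) {
    expect_true(all(diff(hub_trajectory(trf, g)$degree) <= 0))
  }
})

test_that("per-level normalised modularity is recorded for the frontier", {
  tr <- build_module_tree(graph_two_k5())
  expect_equal(tr$levels$level, 0:1)
  expect_equal(tr$levels$q_per_node, tr$levels$q / 10)
  expect_equal(tr$levels$q[1], 0)          # all-in-one partition
  expect_gt(tr$levels$q[2], 0)
})
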