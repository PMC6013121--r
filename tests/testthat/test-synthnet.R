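test_that("hierarchical generator yields b^L nodes and is clean", {
  g <- generate_hierarchical(4, 2)
  expect_equal(igraph::vcount(g), 16)
  g3 <- generate_hierarchical(3, 3)
  expect_equal(igraph::vcount(g3), 27)
  expect_error(generate_hierarchical(10, 6), "cap")
  # already simple: cleaning changes nothing
  expect_equal(igraph::ecount(clean_network(g)), igraph::ecount(g))
  expect_true(igraph::any_loop(g) == FALSE)
  # deterministic
  expect_true(igraph::identical_graphs(generate_hierarchical(4, 3),
                                       generate_hierarchical(4, 3)))
})

test_that("hierarchical generator shows the k^-1 clustering signature", {
  g <- generate_hierarchical(4, 3)
  cl <- suppressMessages(clustering_by_degree(g))
  fit <- fit_loglog(cl$curve, n_boot = 0)
  expect_identical(fit$sign, "negative")
  expect_equal(fit$exponent, 1, tolerance = 0.25)
  # triangles at every scale: every node sits in its replicated base clique
  expect_true(all(igraph::count_triangles(g) > 0))
})

test_that("hierarchical degree distribution is heavy-tailed near the mean-field exponent", {
  g <- generate_hierarchical(4, 4)
  fit <- fit_degree_distribution(igraph::degree(g), n_boot = 0)
  expect_equal(fit$exponent, 1 + log(4) / log(3), tolerance = 0.6)
})

test_that("null models behave as expected and are seed-reproducible", {
  ba <- generate_ba(2000, 3, seed = 5)
  fit <- fit_degree_distribution(igraph::degree(ba), n_boot = 0)
  expect_gte(fit$exponent, 2.5)
  expect_lte(fit$exponent, 3.5)
  expect_identical(igraph::as_edgelist(generate_ba(300, 2, seed = 9)),
                   igraph::as_edgelist(generate_ba(300, 2, seed = 9)))

  er <- generate_er(500, 0.02, seed = 5)
  cl <- suppressMessages(clustering_by_degree(er))
  flat <- suppressWarnings(fit_loglog(cl$curve, n_boot = 0))
  expect_lt(flat$exponent, 0.3)
  expect_identical(igraph::as_edgelist(generate_er(200, 0.05, seed = 4)),
                   igraph::as_edgelist(generate_er(200, 0.05, seed = 4)))
  expect_error(generate_ba(1, 1), "n >= 2")
  expect_error(generate_er(10, 1.5), "p <= 1")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_ba(50, 2, seed = 77))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("the shipped fixture files match the in-code generator", {
  tsv <- system.file("extdata", "planted_fkr_fixture.tsv", package = "fkrnet")
  gt_json <- system.file("extdata", "planted_fkr_ground_truth.json",
                         package = "fkrnet")
  fx <- planted_fkr_fixture()
  shipped <- read_network(tsv, "edgelist")
  expect_setequal(igraph::V(shipped)$name, igraph::V(fx$network)$name)
  expect_equal(igraph::ecount(shipped), igraph::ecount(fx$network))
  el <- igraph::as_edgelist(fx$network)
  expect_true(all(apply(el, 1, function(e) {
    igraph::are_adjacent(shipped, e[1], e[2])
  })))
  gt <- jsonlite::read_json(gt_json, simplifyVector = TRUE)
  expect_setequal(gt$fkr, fx$ground_truth$fkr)
  expect_equal(gt$hub_count, fx$ground_truth$hub_count)
})

test_that("the planted fixture ships a consistent ground truth", {
  fx <- planted_fkr_fixture()
  gt <- fx$ground_truth
  expect_gt(length(gt$fkr), 0)
  expect_true(all(gt$fkr %in% utils::head(rank_hubs(fx$network), gt$hub_count)))
  tr <- build_module_tree(fx$network)
  expect_gte(tr$max_level, gt$min_levels)
  lvl1 <- tr$records[tr$records$level == 1, ]
  got <- lapply(lvl1$id, function(id) sort(tr$members[[id]]))
  want <- lapply(gt$level1_modules, sort)
  for (w in want) {
    expect_true(any(vapply(got, identical, logical(1), w)))
  }
})
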