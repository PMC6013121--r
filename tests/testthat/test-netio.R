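test_that("edge lists are read, cleaned, and parse errors name the line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A B", "B\tC", "A A", "", "B A"), f)
  msgs <- capture_messages(g <- read_network(f, "edgelist"))
  expect_match(paste(msgs, collapse = " "), "1 self-loop")
  expect_match(paste(msgs, collapse = " "), "1 duplicate")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)          # A-B deduped, A-A dropped
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_true(igraph::are_adjacent(g, "B", "C"))

  writeLines(c("A B", "loneToken"), f)
  expect_error(read_network(f, "edgelist"), "line 2")
})

test_that("SIF rows expand one-source-many-targets and keep isolated nodes", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B C", "D"), f)
  g <- read_network(f, "sif")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_true(igraph::are_adjacent(g, "A", "C"))
  expect_false(igraph::are_adjacent(g, "B", "C"))

  writeLines("A pp", f)
  expect_error(read_network(f, "sif"), "line 1")
})

test_that("write/read round-trips preserve node and edge sets in all formats", {
  k3 <- graph_k(3)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  for (fmt in c("edgelist", "sif", "graphml")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(k3, f, fmt)
    back <- read_network(f, fmt)
    expect_setequal(igraph::V(back)$name, igraph::V(k3)$name)
    expect_equal(igraph::ecount(back), 3)
    expect_true(igraph::are_adjacent(back, "K1", "K2"))

    write_network(empty, f, fmt)
    back0 <- read_network(f, fmt)
    expect_equal(igraph::vcount(back0), 0)
  }
  # sif round-trip also keeps isolated nodes
  iso <- igraph::add_vertices(k3, 1, name = "LONER")
  f <- withr::local_tempfile(fileext = ".sif")
  write_network(iso, f, "sif")
  expect_setequal(igraph::V(read_network(f, "sif"))$name,
                  c("K1", "K2", "K3", "LONER"))
})

test_that("cleaning is idempotent", {
  g <- graph_two_k5()
  expect_identical(igraph::ecount(clean_network(g)), igraph::ecount(g))
  expect_true(igraph::identical_graphs(clean_network(clean_network(g)),
                                       clean_network(g)))
})

test_that("seed neighbourhood extraction follows the induced-subgraph rule", {
  star <- graph_star(4)
  sub <- extract_seed_neighborhood(star, "HUB")
  expect_setequal(igraph::V(sub)$name, igraph::V(star)$name)

  sub2 <- extract_seed_neighborhood(star, "L1")
  expect_setequal(igraph::V(sub2)$name, c("L1", "HUB"))
  expect_equal(igraph::ecount(sub2), 1)

  p4 <- graph_path(4)                      # A-B-C-D
  sub3 <- extract_seed_neighborhood(p4, "A")
  expect_setequal(igraph::V(sub3)$name, c("A", "B"))
  expect_equal(igraph::ecount(sub3), 1)

  expect_warning(extract_seed_neighborhood(p4, c("A", "NOPE")), "not in network")
  expect_error(suppressWarnings(extract_seed_neighborhood(p4, "NOPE")),
               "none of the seeds")
})

test_that("seed-incident-only mode drops edges among non-seed neighbours", {
  # triangle B-C-D hanging off seed A: induced keeps B-C, incident-only drops it
  g <- igraph::graph_from_edgelist(
    rbind(c("A", "B"), c("A", "C"), c("B", "C"), c("B", "D"), c("C", "D")),
    directed = FALSE)
  full <- extract_seed_neighborhood(g, "A")
  expect_true(igraph::are_adjacent(full, "B", "C"))
  inc <- extract_seed_neighborhood(g, "A", seed_incident_only = TRUE)
  expect_false(igraph::are_adjacent(inc, "B", "C"))
  expect_setequal(igraph::V(inc)$name, c("A", "B", "C"))
})
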