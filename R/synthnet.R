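# Synthetic substrates. The hierarchical generator is the deterministic
# clique-replication construction (Ravasz-Barabasi style): start from a
# b-node clique, and at each of L-1 replication steps attach b-1 copies of
# the current graph, wiring every peripheral node of the copies to the root
# hub. The result has b^L nodes, triangles at every module scale,
# C(k) ~ k^-1, and a degree exponent near the mean-field hierarchical value
# 1 + ln(b)/ln(b-1) (= 2.26 for b = 4).

#' Deterministic hierarchical scale-free network
#'
#' Clique-replication construction with branching `b` and `L` levels,
#' yielding exactly `b^L` nodes. Deterministic by design so the diagnostic
#' scalings are reliable at testable sizes; `rewire_prob > 0` optionally
#' adds seeded degree-preserving rewiring noise (default off).
#'
#' @param b Clique size / branching factor (>= 3).
#' @param L Number of levels (>= 1).
#' @param seed RNG seed, used only when `rewire_prob > 0`.
#' @param rewire_prob Fraction of edges to rewire (default 0).
#' @return An undirected simple igraph network with nodes `G00001, ...`.
#' @export
generate_hierarchical <- function(b, L, seed = NULL, rewire_prob = 0) {
  stopifnot(b >= 3, L >= 1)
  if (b^L > 1e5) stop("b^L exceeds the 1e5 node cap", call. = FALSE)
  # edge list built on integer ids, root = 1
  combs <- utils::combn(b, 2)
  edges <- rbind(combs[1, ], combs[2, ])       # initial clique
  peripheral <- 2:b
  n_cur <- b
  if (L >= 2) {
    for (step in 2:L) {
      base_edges <- edges
      base_peri <- peripheral
      new_peri <- integer(0)
      for (j in seq_len(b - 1)) {
        off <- j * n_cur
        edges <- cbind(edges, base_edges + off)
        new_peri <- c(new_peri, base_peri + off)
      }
      edges <- cbind(edges, rbind(rep(1L, length(new_peri)), new_peri))
      peripheral <- new_peri
      n_cur <- n_cur * b
    }
  }
  g <- igraph::graph_from_edgelist(t(edges), directed = FALSE)
  igraph::V(g)$name <- sprintf("G%05d", seq_len(igraph::vcount(g)))
  if (rewire_prob > 0) {
    g <- with_seed(seed, igraph::rewire(
      g, igraph::keeping_degseq(niter = ceiling(rewire_prob * igraph::ecount(g)))))
  }
  g <- igraph::simplify(g)
  g$name <- sprintf("hierarchical_b%d_L%d", b, L)
  g
}

#' Barabasi-Albert scale-free null model
#'
#' Seeded preferential-attachment graph (degree exponent near 3, no
#' hierarchical clustering signature).
#'
#' @param n Number of nodes.
#' @param m_attach Edges added per incoming node.
#' @param seed RNG seed.
#' @return An undirected simple igraph network.
#' @export
generate_ba <- function(n, m_attach, seed = NULL) {
  stopifnot(n >= 2, m_attach >= 1)
  g <- with_seed(seed, igraph::sample_pa(n, m = m_attach, directed = FALSE))
  igraph::V(g)$name <- sprintf("G%05d", seq_len(n))
  g <- igraph::simplify(g)
  g$name <- sprintf("ba_n%d_m%d", n, m_attach)
  g
}

#' Erdos-Renyi random null model
#'
#' Seeded G(n, p) graph (Poisson degrees, degree-independent clustering).
#'
#' @param n Number of nodes.
#' @param p Edge probability in (0, 1).
#' @param seed RNG seed.
#' @return An undirected simple igraph network.
#' @export
generate_er <- function(n, p, seed = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  g <- with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("G%05d", seq_len(n))
  g$name <- sprintf("er_n%d", n)
  g
}

#' Planted key-regulator fixture
#'
#' A small deterministic modular network with a known module tree and a
#' known fundamental-key-regulator set, used as ground truth for the FKR
#' trace. Construction: four level-1 modules of deliberately different sizes
#' and densities (so their Hamiltonian energies are pairwise distinct),
#' joined by sparse bridges:
#' \itemize{
#'   \item A — two triangles `A1 A2 A3` and `A4 A5 A6` bridged by the edge
#'     `A1-A4`; splits at level 2 into its two motifs;
#'   \item B — the same double-triangle shape on `B1..B6` densified by a
#'     second bridge `B2-B5` (so A and B have different edge counts and
#'     hence different Hamiltonian energies); also splits into two motifs;
#'   \item C — a K5 `C1..C5`: qualifies (triangles) but is indivisible, so
#'     its hubs terminate without reaching a motif;
#'   \item D — a complete bipartite K2,3 on `D1..D5`: cohesive but
#'     triangle-free, so it never qualifies.
#' }
#' The planted FKRs are `A1`, `A4`, `B1`, `B2`: exactly the top-10 hubs
#' whose branch lies in qualifying modules at every level and ends in a
#' motif (the C and D hubs rank high but their branches terminate in the
#' indivisible K5 and the triangle-free K2,3 respectively).
#'
#' @param seed Unused (the fixture is fully deterministic); accepted so all
#'   generators share a signature.
#' @return List with `network` (igraph) and `ground_truth` (list: `fkr`,
#'   `hub_count`, `min_levels`, `level1_modules`).
#' @export
planted_fkr_fixture <- function(seed = NULL) {
  tri <- function(a, b, c) rbind(c(a, b), c(a, c), c(b, c))
  clique <- function(v) t(utils::combn(v, 2))
  mod_a <- rbind(tri("A1", "A2", "A3"), tri("A4", "A5", "A6"), c("A1", "A4"))
  mod_b <- rbind(tri("B1", "B2", "B3"), tri("B4", "B5", "B6"),
                 c("B1", "B4"), c("B2", "B5"))
  mod_c <- clique(paste0("C", 1:5))
  mod_d <- rbind(c("D1", "D3"), c("D1", "D4"), c("D1", "D5"),
                 c("D2", "D3"), c("D2", "D4"), c("D2", "D5"))
  bridges <- rbind(c("A1", "B1"), c("B1", "C1"), c("C1", "D1"), c("A1", "C1"))
  el <- rbind(mod_a, mod_b, mod_c, mod_d, bridges)
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  g$name <- "planted_fkr_fixture"
  list(
    network = g,
    ground_truth = list(
      fkr = c("A1", "A4", "B1", "B2"),
      hub_count = 10L,
      min_levels = 2L,
      level1_modules = list(
        A = paste0("A", 1:6), B = paste0("B", 1:6),
        C = paste0("C", 1:5), D = paste0("D", 1:5))
    )
  )
}
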