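# Independent brute-force oracles. These deliberately avoid the package's own
# code paths (and igraph's algorithms): shortest paths are enumerated with a
# hand-rolled BFS, modularity evaluated straight from its definition, the
# principal eigenpair taken from base::eigen.

# --- small named graphs used across tests -----------------------------------

graph_k <- function(n, prefix = "K") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

graph_star <- function(leaves) {
  g <- igraph::make_star(leaves + 1, mode = "undirected")
  igraph::V(g)$name <- c("HUB", paste0("L", seq_len(leaves)))
  g
}

graph_path <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- LETTERS[seq_len(n)]
  g
}

# paw: triangle a-b-c plus pendant d attached to a
graph_paw <- function() {
  igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("a", "d")),
    directed = FALSE)
}

# two K5 cliques joined by a single bridge edge N1-N6
graph_two_k5 <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("N", 1:10)
  g
}

# Random connected G(n, p) graph; only igraph plumbing (adjacency container),
# the randomness is plain runif so the construction is easy to audit.
random_connected_graph <- function(n, p = 0.35) {
  repeat {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p) A[i, j] <- A[j, i] <- 1
      }
    }
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::ecount(g) > 0 && igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      return(g)
    }
  }
}

# --- BFS machinery (hand-rolled) --------------------------------------------

adj_list <- function(g) {
  lapply(seq_len(igraph::vcount(g)), function(i) {
    as.integer(igraph::neighbors(g, i))
  })
}

bfs_dist_counts <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  nsp <- rep(0, n)
  d[s] <- 0
  nsp[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.infinite(d[v])) {
          d[v] <- d[u] + 1
          nxt <- c(nxt, v)
        }
        if (d[v] == d[u] + 1) nsp[v] <- nsp[v] + nsp[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, nsp = nsp)
}

# Betweenness from the pair-counting identity: v lies on a geodesic s-t iff
# d(s,v) + d(v,t) = d(s,t); its share is nsp(s,v) * nsp(v,t) / nsp(s,t).
oracle_betweenness <- function(g) {
  adj <- adj_list(g)
  n <- length(adj)
  bf <- lapply(seq_len(n), function(s) bfs_dist_counts(adj, s))
  b <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (t <= s) next
      dst <- bf[[s]]$d[t]
      if (is.infinite(dst)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (bf[[s]]$d[v] + bf[[t]]$d[v] == dst) {
          b[v] <- b[v] + bf[[s]]$nsp[v] * bf[[t]]$nsp[v] / bf[[s]]$nsp[t]
        }
      }
    }
  }
  M <- (n - 1) * (n - 2) / 2
  stats::setNames(b / M, igraph::V(g)$name)
}

oracle_closeness <- function(g) {
  adj <- adj_list(g)
  n <- length(adj)
  cc <- vapply(seq_len(n), function(i) {
    d <- bfs_dist_counts(adj, i)$d[-i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  stats::setNames(cc, igraph::V(g)$name)
}

oracle_eigenvector <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  stats::setNames(v / sqrt(sum(v^2)), igraph::V(g)$name)
}

# Modularity straight from Q = sum_c [ e_c/m - (d_c/2m)^2 ].
oracle_modularity <- function(g, memb) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(g)
  if (!is.null(names(memb))) memb <- memb[igraph::V(g)$name]
  q <- 0
  for (c in unique(memb)) {
    e_c <- sum(memb[el[, 1]] == c & memb[el[, 2]] == c)
    d_c <- sum(deg[memb == c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Exhaustive modularity-maximising bipartition over all 2^(n-1) sign vectors.
oracle_best_bipartition <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  best_memb <- NULL
  n_best <- 0
  for (mask in 0:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1)] + 1L)
    q <- oracle_modularity(g, memb)
    if (q > best + 1e-12) {
      best <- q
      best_memb <- memb
      n_best <- 1L
    } else if (abs(q - best) < 1e-12) {
      n_best <- n_best + 1L
    }
  }
  list(q = best, membership = best_memb, unique = n_best == 1L)
}

same_partition <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Brute-force (CN, LCL) per edge via explicit neighbourhood set operations.
oracle_cn_lcl <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  nbrs <- lapply(igraph::V(g)$name, function(v) {
    igraph::neighbors(g, v)$name
  })
  names(nbrs) <- igraph::V(g)$name
  t(apply(el, 1, function(e) {
    cn <- setdiff(intersect(nbrs[[e[1]]], nbrs[[e[2]]]), e)
    lcl <- 0
    if (length(cn) >= 2) {
      prs <- utils::combn(cn, 2)
      lcl <- sum(apply(prs, 2, function(p) p[2] %in% nbrs[[p[1]]]))
    }
    c(cn = length(cn), lcl = lcl)
  }))
}
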