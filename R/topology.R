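# Degree-indexed topological quantities: P(k), C(k), Cn(k) and the three
# centralities, each exposed per node and aggregated into a degree curve.

degree_curve <- function(k, y, n_k, metric) {
  ord <- order(k)
  out <- data.frame(k = as.integer(k[ord]), y = as.numeric(y[ord]),
                    n_k = as.integer(n_k[ord]))
  attr(out, "metric") <- metric
  class(out) <- c("degree_curve", "data.frame")
  out
}

#' @export
print.degree_curve <- function(x, ...) {
  cat("<degree_curve> metric:", attr(x, "metric"),
      "-", nrow(x), "degree classes\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Degree distribution P(k)
#'
#' The fraction of nodes with degree `k`: `P(k) = n_k / N`. Probabilities sum
#' to one over the observed degree classes.
#'
#' @param net An undirected simple igraph network.
#' @return A `degree_curve` data frame with columns `k`, `y` (= P(k)), `n_k`.
#' @export
degree_distribution_curve <- function(net) {
  check_network(net)
  if (igraph::vcount(net) == 0) stop("empty network", call. = FALSE)
  deg <- igraph::degree(net)
  tab <- table(deg)
  k <- as.integer(names(tab))
  degree_curve(k, as.integer(tab) / length(deg), as.integer(tab), "P(k)")
}

#' Clustering coefficient and its degree curve
#'
#' Per-node clustering `C_i = 2 e_i / (k_i (k_i - 1))`, where `e_i` counts
#' edges among the neighbours of node `i`. Nodes with degree < 2 have no
#' defined clustering and are excluded from both the node table and the
#' degree curve (their count is reported via `message()`). The curve is the
#' arithmetic mean of `C` over nodes of equal degree.
#'
#' @param net An undirected simple igraph network.
#' @return A list with `nodes` (data frame `gene`, `k`, `clustering`) and
#'   `curve` (a `degree_curve`).
#' @export
clustering_by_degree <- function(net) {
  check_network(net)
  deg <- igraph::degree(net)
  cl <- igraph::transitivity(net, type = "local", isolates = "NaN")
  ok <- deg >= 2
  if (any(!ok)) message(sum(!ok), " node(s) with degree < 2 excluded from C(k)")
  nodes <- data.frame(gene = igraph::V(net)$name[ok], k = as.integer(deg[ok]),
                      clustering = cl[ok], row.names = NULL)
  agg <- aggregate(clustering ~ k, data = nodes, FUN = mean)
  cnt <- aggregate(clustering ~ k, data = nodes, FUN = length)
  list(nodes = nodes,
       curve = degree_curve(agg$k, agg$clustering, cnt$clustering, "C(k)"))
}

#' Neighbourhood connectivity curve Cn(k)
#'
#' For each node, the mean degree of its neighbours; averaged over nodes of
#' equal degree. A decreasing curve (negative fitted exponent) signals
#' disassortativity — hubs preferentially attach to low-degree nodes.
#'
#' @param net An undirected simple igraph network.
#' @return A `degree_curve`.
#' @export
neighborhood_connectivity <- function(net) {
  check_network(net)
  deg <- igraph::degree(net)
  nn <- vapply(seq_len(igraph::vcount(net)), function(i) {
    nb <- as.integer(igraph::neighbors(net, i))
    if (length(nb) == 0) NaN else mean(deg[nb])
  }, numeric(1))
  ok <- !is.nan(nn)
  df <- data.frame(k = as.integer(deg[ok]), nn = nn[ok])
  agg <- aggregate(nn ~ k, data = df, FUN = mean)
  cnt <- aggregate(nn ~ k, data = df, FUN = length)
  degree_curve(agg$k, agg$nn, cnt$nn, "Cn(k)")
}

#' Normalised betweenness centrality
#'
#' The fraction of geodesics between every other node pair that pass through
#' each node, summed over pairs with fractional attribution when several
#' shortest paths exist, and normalised by the number of pairs excluding the
#' node, `M = (N-1)(N-2)/2`, so values lie in `[0, 1]`.
#'
#' @param net An undirected simple igraph network.
#' @return A named numeric vector (one value per node).
#' @export
betweenness_centrality <- function(net) {
  check_network(net)
  n <- igraph::vcount(net)
  if (n < 3) {
    warning("fewer than 3 nodes: betweenness is identically zero")
    return(stats::setNames(rep(0, n), igraph::V(net)$name))
  }
  igraph::betweenness(net, directed = FALSE, normalized = TRUE)
}

#' Closeness centrality (per connected component)
#'
#' Reciprocal of the mean geodesic distance from each node to the nodes
#' reachable from it: `C_C(i) = n_i / sum_j d_ij`, with `n_i` the number of
#' nodes in `i`'s component other than `i` itself. Isolated nodes get 0 with
#' a warning. No harmonic variant is used.
#'
#' @param net An undirected simple igraph network.
#' @return A named numeric vector (one value per node).
#' @export
closeness_centrality <- function(net) {
  check_network(net)
  n <- igraph::vcount(net)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  d <- igraph::distances(net)
  cc <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) 0 else length(di) / sum(di)
  }, numeric(1))
  if (any(cc == 0)) warning(sum(cc == 0), " isolated node(s) assigned closeness 0")
  stats::setNames(cc, igraph::V(net)$name)
}

#' Eigenvector centrality by power iteration
#'
#' The principal eigenvector of the adjacency matrix, computed on the largest
#' connected component (nodes outside it get 0, with a message). The
#' iteration runs on `A + I` — same eigenvectors as `A`, but the shift makes
#' the principal eigenvalue strictly dominant even on bipartite components —
#' from a deterministic all-ones start, until the residual
#' `max|A v - lambda v|` falls below `tol`. The returned vector is
#' nonnegative with unit L2 norm over the component; the principal
#' eigenvalue of `A` (Rayleigh quotient) is attached as attribute `lambda`.
#'
#' @param net An undirected simple igraph network.
#' @param tol Convergence tolerance on the eigen-residual (default 1e-10).
#' @param max_iter Maximum number of power iterations (default 10000).
#' @return A named numeric vector with attribute `lambda`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000) {
  check_network(net)
  n <- igraph::vcount(net)
  out <- stats::setNames(rep(0, n), igraph::V(net)$name)
  comp <- igraph::components(net)
  if (n == 0 || max(comp$csize) < 2) {
    attr(out, "lambda") <- 0
    return(out)
  }
  main <- which(comp$membership == which.max(comp$csize))
  if (length(main) < n) {
    message(n - length(main), " node(s) outside the largest component get ",
            "eigenvector centrality 0")
  }
  sub <- igraph::induced_subgraph(net, main)
  A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
  m <- nrow(A)
  v <- rep(1 / sqrt(m), m)
  lambda <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- as.numeric(A %*% v) + v           # (A + I) v
    w <- w / sqrt(sum(w^2))
    Av <- as.numeric(A %*% w)
    lambda <- sum(w * Av)                  # Rayleigh quotient on A
    if (max(abs(Av - lambda * w)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  if (!converged) {
    stop("eigenvector centrality did not converge in ", max_iter,
         " iterations", call. = FALSE)
  }
  out[main] <- abs(v)
  attr(out, "lambda") <- lambda
  out
}

#' Aggregate a per-node metric into a degree curve
#'
#' Arithmetic mean of the metric over nodes of equal degree — the aggregation
#' used to plot centralities against `k`.
#'
#' @param values Named numeric vector covering all nodes of `net`.
#' @param net An undirected simple igraph network.
#' @param metric Label for the curve.
#' @return A `degree_curve`.
#' @export
metric_vs_degree <- function(values, net, metric = "metric") {
  check_network(net)
  nm <- igraph::V(net)$name
  if (!all(nm %in% names(values))) {
    stop("`values` must cover every node of the network", call. = FALSE)
  }
  df <- data.frame(k = as.integer(igraph::degree(net)), y = as.numeric(values[nm]))
  agg <- aggregate(y ~ k, data = df, FUN = mean)
  cnt <- aggregate(y ~ k, data = df, FUN = length)
  degree_curve(agg$k, agg$y, cnt$y, metric)
}

#' All six per-node topological metrics
#'
#' Convenience wrapper returning one row per node with degree, clustering,
#' mean neighbour degree, and the three centralities.
#'
#' @param net An undirected simple igraph network.
#' @param tol,max_iter Passed to [eigenvector_centrality()].
#' @return A data frame with columns `gene`, `k`, `clustering`,
#'   `neighborhood_connectivity`, `betweenness`, `closeness`, `eigenvector`.
#' @export
node_metric_table <- function(net, tol = 1e-10, max_iter = 10000) {
  check_network(net)
  nm <- igraph::V(net)$name
  deg <- igraph::degree(net)
  cl <- igraph::transitivity(net, type = "local", isolates = "NaN")
  nn <- vapply(seq_len(igraph::vcount(net)), function(i) {
    nb <- as.integer(igraph::neighbors(net, i))
    if (length(nb) == 0) NaN else mean(deg[nb])
  }, numeric(1))
  data.frame(
    gene = nm,
    k = as.integer(deg),
    clustering = cl,
    neighborhood_connectivity = nn,
    betweenness = as.numeric(suppressWarnings(betweenness_centrality(net))),
    closeness = as.numeric(suppressWarnings(closeness_centrality(net))),
    eigenvector = as.numeric(eigenvector_centrality(net, tol, max_iter)),
    row.names = NULL
  )
}
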