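# Local community paradigm (LCP) statistics. For each *existing* edge (x,y):
# CN = number of common neighbours of x and y, LCL = number of edges whose
# both endpoints are common neighbours (so LCL <= CN(CN-1)/2). LCP-corr is
# the Pearson correlation of CN and LCL over edges with CN > 1; large values
# (>= 0.8) mark compact, fast-communicating modules.

#' CN and LCL of one edge
#'
#' @param net An undirected simple igraph network.
#' @param edge Length-2 character vector: the edge's endpoints.
#' @return Named numeric vector `c(cn = , lcl = )`.
#' @export
edge_cn_lcl <- function(net, edge) {
  check_network(net)
  stopifnot(length(edge) == 2)
  if (!all(edge %in% igraph::V(net)$name)) {
    stop("unknown node in edge: ", paste(edge, collapse = "-"), call. = FALSE)
  }
  if (!igraph::are_adjacent(net, edge[[1]], edge[[2]])) {
    stop("edge not present: ", paste(edge, collapse = "-"), call. = FALSE)
  }
  nb1 <- igraph::neighbors(net, edge[[1]])$name
  nb2 <- igraph::neighbors(net, edge[[2]])$name
  cn <- setdiff(intersect(nb1, nb2), edge)
  lcl <- if (length(cn) >= 2) {
    igraph::ecount(igraph::induced_subgraph(net, cn))
  } else {
    0L
  }
  c(cn = length(cn), lcl = as.numeric(lcl))
}

#' LCP decomposition of a network
#'
#' Computes (CN, LCL) for every edge and the LCP correlation over edges with
#' CN > 1. The correlation is flagged undefined when fewer than two edges
#' qualify or either variable has zero variance.
#'
#' @param net An undirected simple igraph network.
#' @return An `lcp_result`: list with `edges` (data frame `from`, `to`,
#'   `cn`, `lcl`), `corr`, `defined`, `n_edges_used`, `max_cn`.
#' @export
lcp_correlation <- function(net) {
  check_network(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  nm <- igraph::V(net)$name
  adj <- igraph::as_adj_list(net)
  adj <- lapply(adj, as.integer)
  n_e <- nrow(el)
  cn <- integer(n_e)
  lcl <- numeric(n_e)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  for (i in seq_len(n_e)) {
    u <- el[i, 1]
    v <- el[i, 2]
    common <- setdiff(intersect(adj[[u]], adj[[v]]), c(u, v))
    cn[i] <- length(common)
    if (cn[i] >= 2) {
      lcl[i] <- sum(A[common, common]) / 2
    }
  }
  edges <- data.frame(from = nm[el[, 1]], to = nm[el[, 2]],
                      cn = cn, lcl = lcl, stringsAsFactors = FALSE)
  qual <- edges[edges$cn > 1, ]
  defined <- nrow(qual) >= 2 && sd(qual$cn) > 0 && sd(qual$lcl) > 0
  corr <- if (defined) cor(qual$cn, qual$lcl) else NA_real_
  structure(list(edges = edges, corr = corr, defined = defined,
                 n_edges_used = nrow(qual),
                 max_cn = if (n_e > 0) max(cn) else NA_integer_),
            class = "lcp_result")
}

#' @export
print.lcp_result <- function(x, ...) {
  cat("<lcp_result>", nrow(x$edges), "edges;",
      x$n_edges_used, "with CN > 1; LCP-corr:",
      if (x$defined) signif(x$corr, 4) else "undefined", "\n")
  invisible(x)
}

#' Classify modules by LCP correlation strength
#'
#' Each module of the tree gets its own induced-subgraph LCP correlation and
#' a label: `strong` when LCP-corr >= `threshold`, `weak` below it,
#' `undefined` when the correlation itself is undefined (e.g. a bare motif
#' has no CN > 1 edges).
#'
#' @param tree A `module_tree`.
#' @param threshold Strong/weak cut, default 0.8.
#' @return Data frame: `id`, `level`, `n_nodes`, `corr`, `n_edges_used`,
#'   `max_cn`, `label`.
#' @export
classify_modules <- function(tree, threshold = 0.8) {
  stopifnot(inherits(tree, "module_tree"))
  rows <- lapply(seq_len(nrow(tree$records)), function(i) {
    id <- tree$records$id[i]
    sub <- igraph::induced_subgraph(tree$graph, tree$members[[id]])
    r <- lcp_correlation(sub)
    data.frame(id = id, level = tree$records$level[i],
               n_nodes = tree$records$n_nodes[i],
               corr = r$corr, n_edges_used = r$n_edges_used,
               max_cn = r$max_cn,
               label = if (!r$defined) "undefined"
                       else if (r$corr >= threshold) "strong" else "weak",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative LCP correlation along a gene's branch
#'
#' `P_LCP(s) = x_s / x_N`: the LCP correlation of the branch module at level
#' `s` divided by the full network's LCP correlation. Undefined module
#' correlations propagate as `NA` with `defined = FALSE`.
#'
#' @param tree A `module_tree`.
#' @param gene Gene symbol whose branch to follow.
#' @param full_corr Full-network LCP correlation; computed from the tree's
#'   graph when omitted.
#' @return Data frame: `level`, `module`, `corr`, `p_lcp`, `defined`.
#' @export
relative_lcp <- function(tree, gene, full_corr = NULL) {
  stopifnot(inherits(tree, "module_tree"))
  if (is.null(full_corr)) {
    full <- lcp_correlation(tree$graph)
    if (!full$defined) stop("full-network LCP correlation is undefined",
                            call. = FALSE)
    full_corr <- full$corr
  }
  if (!is.finite(full_corr) || full_corr == 0) {
    stop("full-network LCP correlation must be nonzero", call. = FALSE)
  }
  ids <- branch_modules(tree, gene)
  rows <- lapply(ids, function(id) {
    sub <- igraph::induced_subgraph(tree$graph, tree$members[[id]])
    r <- lcp_correlation(sub)
    data.frame(level = tree$records$level[tree$records$id == id],
               module = id, corr = r$corr,
               p_lcp = if (r$defined) r$corr / full_corr else NA_real_,
               defined = r$defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
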