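# Recursive community decomposition. The partitioner is Newman's
# leading-eigenvector method (LEV), implemented here directly: recursive
# spectral bisection on the modularity matrix B = A - k k^T / 2m, using the
# generalized (subset) form for nested splits. The module tree then applies
# LEV afresh to each qualifying module's induced subgraph until only motifs
# (triangles) or indivisible/triangle-free modules remain.

# Leading eigenpair of a dense symmetric matrix, deterministically.
lev_leading_eigen <- function(B) {
  e <- eigen(B, symmetric = TRUE)
  i <- which.max(e$values)
  v <- e$vectors[, i]
  # fix the sign convention so results do not depend on LAPACK's choice
  j <- which(abs(v) > 1e-12)[1]
  if (!is.na(j) && v[j] < 0) v <- -v
  list(value = e$values[i], vector = v)
}

# Recursive sign-split of one connected vertex subset. `B` is the full
# modularity matrix of the component, `idx` the subset (integer indices into
# B), `m` the component's edge count. Returns a list of integer vectors.
lev_split <- function(B, idx, m, eps = 1e-8) {
  if (length(idx) < 2) return(list(idx))
  Bg <- B[idx, idx, drop = FALSE]
  # generalized modularity matrix: remove row sums on the diagonal so the
  # split is scored within the subset only
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  le <- lev_leading_eigen(Bg)
  if (le$value <= eps) return(list(idx))
  s <- ifelse(le$vector >= 0, 1, -1)   # ties (components ~ 0) go positive
  if (all(s == 1) || all(s == -1)) return(list(idx))
  dq <- as.numeric(t(s) %*% Bg %*% s) / (4 * m)
  if (dq <= 0) return(list(idx))
  c(lev_split(B, idx[s == 1], m, eps),
    lev_split(B, idx[s == -1], m, eps))
}

#' Partition a network with the leading-eigenvector method
#'
#' Newman's spectral community detection: the modularity matrix
#' `B = A - k k^T / 2m` is bisected recursively by the sign pattern of its
#' leading eigenvector, a split being accepted only when the leading
#' eigenvalue exceeds `eps` and the modularity gain is positive. Disconnected
#' inputs are pre-split into connected components. Eigen-solves are dense and
#' deterministic; eigenvector entries indistinguishable from zero join the
#' positive side.
#'
#' @param net An undirected simple igraph network.
#' @param eps Threshold on the leading eigenvalue below which a module is
#'   declared indivisible (default 1e-8).
#' @return An `igraph` communities-style membership: a named integer vector
#'   mapping each node to a community id (1-based, in first-seen order).
#' @export
leading_eigenvector_partition <- function(net, eps = 1e-8) {
  check_network(net)
  n <- igraph::vcount(net)
  if (n == 0) return(stats::setNames(integer(0), character(0)))
  comp <- igraph::components(net)
  membership <- integer(n)
  next_id <- 1L
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    if (length(vids) == 1) {
      membership[vids] <- next_id
      next_id <- next_id + 1L
      next
    }
    sub <- igraph::induced_subgraph(net, vids)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
    k <- rowSums(A)
    m <- sum(k) / 2
    B <- A - outer(k, k) / (2 * m)
    parts <- lev_split(B, seq_along(vids), m, eps)
    for (p in parts) {
      membership[vids[p]] <- next_id
      next_id <- next_id + 1L
    }
  }
  stats::setNames(membership, igraph::V(net)$name)
}

#' Newman modularity of a partition
#'
#' `Q = sum_c [ e_c/m - (sum of degrees in c / 2m)^2 ]`, evaluated through
#' igraph. Every node must be covered by the partition.
#'
#' @param net An undirected simple igraph network.
#' @param membership Named (or positionally aligned) community id vector.
#' @return The scalar modularity Q.
#' @export
modularity_q <- function(net, membership) {
  check_network(net)
  if (!is.null(names(membership))) {
    if (!all(igraph::V(net)$name %in% names(membership))) {
      stop("partition does not cover every node", call. = FALSE)
    }
    membership <- membership[igraph::V(net)$name]
  } else if (length(membership) != igraph::vcount(net)) {
    stop("partition does not cover every node", call. = FALSE)
  }
  igraph::modularity(net, as.integer(as.factor(membership)))
}

has_triangle <- function(net) {
  igraph::vcount(net) >= 3 && sum(igraph::count_triangles(net)) > 0
}

#' Build the recursive module tree of a network
#'
#' Level 0 is the whole network. Every module that *qualifies* as a community
#' (contains at least one triangle, the `G(3,3)` motif criterion) and is not
#' itself a motif (exactly 3 nodes and 3 edges) is re-partitioned standalone:
#' [leading_eigenvector_partition()] is applied to its induced subgraph, and
#' if more than one community results they become its children at the next
#' level. Recursion stops at motifs, at triangle-free modules, and at modules
#' the partitioner leaves whole.
#'
#' @param net An undirected simple igraph network.
#' @param eps Eigenvalue threshold passed to the partitioner.
#' @return A `module_tree` object: list with `records` (data frame: `id`,
#'   `level`, `parent`, `n_nodes`, `n_edges`, `qualifies`, `is_motif`,
#'   `n_children`), `members` (named list of character vectors), `graph`
#'   (the input network), `max_level`, and `levels` (per-level summary with
#'   normalised modularity `q_per_node` of the level's frontier partition).
#' @export
build_module_tree <- function(net, eps = 1e-8) {
  check_network(net)
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network", call. = FALSE)
  records <- list()
  members <- list()
  queue <- list(list(id = "M0", level = 0L, parent = NA_character_,
                     nodes = igraph::V(net)$name))
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    sub <- igraph::induced_subgraph(net, cur$nodes)
    nn <- igraph::vcount(sub)
    ne <- igraph::ecount(sub)
    qual <- has_triangle(sub)
    motif <- (nn == 3L && ne == 3L)
    children <- character(0)
    if (qual && !motif && nn > 3) {
      part <- leading_eigenvector_partition(sub, eps = eps)
      if (length(unique(part)) > 1) {
        for (cid in sort(unique(part))) {
          child_id <- paste0(cur$id, ".", cid)
          children <- c(children, child_id)
          queue[[length(queue) + 1L]] <- list(
            id = child_id, level = cur$level + 1L, parent = cur$id,
            nodes = names(part)[part == cid])
        }
      }
    }
    records[[cur$id]] <- data.frame(
      id = cur$id, level = cur$level, parent = cur$parent,
      n_nodes = nn, n_edges = ne, qualifies = qual, is_motif = motif,
      n_children = length(children), stringsAsFactors = FALSE)
    members[[cur$id]] <- cur$nodes
  }
  rec <- do.call(rbind, records)
  rownames(rec) <- NULL
  tree <- structure(list(records = rec, members = members, graph = net,
                         max_level = max(rec$level)),
                    class = "module_tree")
  tree$levels <- module_tree_level_summary(tree)
  tree
}

# Frontier partition at level s: each node belongs to its deepest containing
# module with level <= s. Used for the per-level normalised modularity.
frontier_partition <- function(tree, s) {
  rec <- tree$records
  part <- stats::setNames(rep("M0", igraph::vcount(tree$graph)),
                          igraph::V(tree$graph)$name)
  for (lev in seq_len(s)) {
    at <- rec$id[rec$level == lev]
    for (id in at) part[tree$members[[id]]] <- id
  }
  part
}

module_tree_level_summary <- function(tree) {
  n <- igraph::vcount(tree$graph)
  do.call(rbind, lapply(0:tree$max_level, function(s) {
    part <- frontier_partition(tree, s)
    q <- modularity_q(tree$graph, part)
    data.frame(level = s,
               n_modules = sum(tree$records$level == s),
               q = q, q_per_node = q / n)
  }))
}

#' @export
print.module_tree <- function(x, ...) {
  cat("<module_tree>", nrow(x$records), "modules over levels 0..",
      x$max_level, "on", igraph::vcount(x$graph), "nodes\n")
  print(x$levels, row.names = FALSE)
  invisible(x)
}

# Modules on one gene's branch, root first.
branch_modules <- function(tree, gene) {
  rec <- tree$records
  ids <- character(0)
  cur <- "M0"
  if (!(gene %in% tree$members[["M0"]])) {
    stop("gene not in the network: ", gene, call. = FALSE)
  }
  repeat {
    ids <- c(ids, cur)
    kids <- rec$id[!is.na(rec$parent) & rec$parent == cur]
    nxt <- kids[vapply(kids, function(k) gene %in% tree$members[[k]], logical(1))]
    if (length(nxt) == 0) break
    cur <- nxt[[1]]
  }
  ids
}

#' Trace a hub through the module tree
#'
#' For each level of the tree that contains the gene, reports the containing
#' module, the gene's degree within that module's induced subgraph (its
#' "popularity"), and its dense popularity rank within the module (ties
#' share a rank). The trajectory ends where the gene's branch stops
#' recursing. In-module degree is non-increasing with level, since induced
#' subgraphs only lose edges.
#'
#' @param tree A `module_tree`.
#' @param gene A gene symbol present in the network.
#' @return A data frame of class `hub_trajectory`: `gene`, `level`,
#'   `module`, `degree`, `rank`, `module_nodes`, `module_edges`.
#' @export
hub_trajectory <- function(tree, gene) {
  stopifnot(inherits(tree, "module_tree"))
  ids <- branch_modules(tree, gene)
  rows <- lapply(ids, function(id) {
    sub <- igraph::induced_subgraph(tree$graph, tree$members[[id]])
    deg <- igraph::degree(sub)
    d <- deg[[gene]]
    data.frame(gene = gene,
               level = tree$records$level[tree$records$id == id],
               module = id, degree = as.integer(d),
               rank = dense_rank_desc(as.numeric(deg))[[match(gene, names(deg))]],
               module_nodes = igraph::vcount(sub),
               module_edges = igraph::ecount(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hub_trajectory", "data.frame")
  out
}
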