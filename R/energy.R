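# Constant Potts Model (CPM) energetics. The Hamiltonian of a partition is
#   H = -sum_c (e_c - gamma_c * n_c^2),
# with e_c, n_c the edge and node counts of community c and gamma_c the
# resolution. The default takes the resolution bound gamma_c = 1/n_c^2
# literally per community, so each community contributes -(e_c - 1) and the
# total collapses to the closed form H = K - sum_c e_c for K communities; a
# conventional global-gamma mode is also provided.

#' Hamiltonian energy of a partition
#'
#' @param net An undirected simple igraph network.
#' @param membership Named community id vector covering every node (a single
#'   community when omitted).
#' @param gamma_mode `"percommunity"` (default, `gamma_c = 1/n_c^2`) or
#'   `"global"`.
#' @param gamma Resolution used when `gamma_mode = "global"`.
#' @return An `energy_result`: list with `communities` (data frame
#'   `community`, `n_c`, `e_c`, `gamma`, `h`), `total`, `gamma_mode`.
#' @export
hamiltonian <- function(net, membership = NULL,
                        gamma_mode = c("percommunity", "global"),
                        gamma = NULL) {
  check_network(net)
  gamma_mode <- match.arg(gamma_mode)
  if (gamma_mode == "global" && (is.null(gamma) || !is.finite(gamma))) {
    stop("global gamma mode needs a numeric `gamma`", call. = FALSE)
  }
  nm <- igraph::V(net)$name
  if (is.null(membership)) {
    membership <- stats::setNames(rep(1L, length(nm)), nm)
  }
  if (!is.null(names(membership))) {
    if (!all(nm %in% names(membership))) {
      stop("partition does not cover every node", call. = FALSE)
    }
    membership <- membership[nm]
  } else if (length(membership) != length(nm)) {
    stop("partition does not cover every node", call. = FALSE)
  }
  comms <- split(nm, membership)
  if (any(lengths(comms) == 0)) stop("empty community", call. = FALSE)
  rows <- lapply(names(comms), function(cid) {
    v <- comms[[cid]]
    n_c <- length(v)
    e_c <- igraph::ecount(igraph::induced_subgraph(net, v))
    g <- if (gamma_mode == "percommunity") 1 / n_c^2 else gamma
    data.frame(community = cid, n_c = n_c, e_c = e_c, gamma = g,
               h = -(e_c - g * n_c^2), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(communities = tab, total = sum(tab$h),
                 gamma_mode = gamma_mode), class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat("<energy_result>", nrow(x$communities), "community(ies), gamma mode:",
      x$gamma_mode, " total H:", signif(x$total, 6), "\n")
  invisible(x)
}

#' Energy per node of a module
#'
#' `P_H = H / N`: the module's Hamiltonian (treated as a single community)
#' divided by its node count.
#'
#' @param module An undirected simple igraph network (a module's induced
#'   subgraph).
#' @param gamma_mode,gamma As in [hamiltonian()].
#' @return Scalar `P_H`.
#' @export
energy_per_node <- function(module, gamma_mode = c("percommunity", "global"),
                            gamma = NULL) {
  check_network(module)
  if (igraph::vcount(module) == 0) stop("empty module", call. = FALSE)
  h <- hamiltonian(module, gamma_mode = gamma_mode, gamma = gamma)
  h$total / igraph::vcount(module)
}

#' Per-module energy table of a module tree
#'
#' Hamiltonian (single-community) and per-node energy for every module.
#'
#' @param tree A `module_tree`.
#' @param gamma_mode,gamma As in [hamiltonian()].
#' @return Data frame: `id`, `level`, `n_nodes`, `n_edges`, `h`, `p_h`.
#' @export
module_energy_table <- function(tree, gamma_mode = c("percommunity", "global"),
                                gamma = NULL) {
  stopifnot(inherits(tree, "module_tree"))
  rows <- lapply(seq_len(nrow(tree$records)), function(i) {
    sub <- igraph::induced_subgraph(tree$graph, tree$members[[tree$records$id[i]]])
    h <- hamiltonian(sub, gamma_mode = gamma_mode, gamma = gamma)$total
    data.frame(id = tree$records$id[i], level = tree$records$level[i],
               n_nodes = tree$records$n_nodes[i],
               n_edges = tree$records$n_edges[i],
               h = h, p_h = h / tree$records$n_nodes[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Energy heterogeneity across one level of the tree
#'
#' Checks, for the children at level `level` against their parents at
#' `level - 1`: (a) whether the summed child energy is below the parent
#' energy, and (b) whether the child energies are pairwise distinct
#' (tolerance 1e-9). Because the normalisation of the compared quantities is
#' a modelling choice, both the raw Hamiltonian and the per-node variant are
#' evaluated and reported.
#'
#' @param tree A `module_tree`.
#' @param level Child level (>= 1).
#' @param gamma_mode,gamma As in [hamiltonian()].
#' @param tol Distinctness tolerance.
#' @return Data frame, one row per parent with children at `level`:
#'   `parent`, `n_children`, `sum_child_h`, `parent_h`, `sum_less_raw`,
#'   `distinct_raw`, `sum_child_ph`, `parent_ph`, `sum_less_per_node`,
#'   `distinct_per_node`.
#' @export
energy_heterogeneity_check <- function(tree, level = 1,
                                       gamma_mode = c("percommunity", "global"),
                                       gamma = NULL, tol = 1e-9) {
  stopifnot(inherits(tree, "module_tree"), level >= 1)
  if (level > tree$max_level) stop("tree has no level ", level, call. = FALSE)
  tab <- module_energy_table(tree, gamma_mode = gamma_mode, gamma = gamma)
  rec <- tree$records
  kids <- rec[rec$level == level & !is.na(rec$parent), ]
  rows <- lapply(unique(kids$parent), function(p) {
    ch <- kids$id[kids$parent == p]
    hc <- tab$h[match(ch, tab$id)]
    pc <- tab$p_h[match(ch, tab$id)]
    hp <- tab$h[match(p, tab$id)]
    pp <- tab$p_h[match(p, tab$id)]
    distinct <- function(x) {
      length(x) < 2 || min(stats::dist(x)) > tol
    }
    data.frame(parent = p, n_children = length(ch),
               sum_child_h = sum(hc), parent_h = hp,
               sum_less_raw = sum(hc) < hp,
               distinct_raw = distinct(hc),
               sum_child_ph = sum(pc), parent_ph = pp,
               sum_less_per_node = sum(pc) < pp,
               distinct_per_node = distinct(pc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
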