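# Fundamental key regulators (FKRs): leading hubs that stay inside
# qualifying (triangle-containing) modules at every level of the module tree
# and whose branch terminates in a motif — hubs "deeply rooted" from the
# whole network down to the fundamental regulating unit.

#' Per-level regulating probability of a gene
#'
#' `P_FKR(s) = x^[s] / N^[s]`: the gene's degree within its containing
#' module at level `s`, divided by that module's edge count. A module with
#' zero edges yields `NA` with `defined = FALSE`.
#'
#' @param tree A `module_tree`.
#' @param gene Gene symbol present in the network.
#' @return Data frame: `level`, `module`, `degree`, `module_edges`,
#'   `p_fkr`, `defined`.
#' @export
fkr_probability <- function(tree, gene) {
  traj <- hub_trajectory(tree, gene)
  p <- ifelse(traj$module_edges > 0, traj$degree / traj$module_edges, NA_real_)
  data.frame(level = traj$level, module = traj$module, degree = traj$degree,
             module_edges = traj$module_edges, p_fkr = p,
             defined = traj$module_edges > 0, stringsAsFactors = FALSE)
}

#' Identify fundamental key regulators among the leading hubs
#'
#' Takes the top `hub_count` hubs (degree ranking with lexicographic
#' tie-break) and keeps those whose branch through the module tree lies in a
#' qualifying module at every level and terminates in a motif (3 nodes, 3
#' edges). By default motif membership suffices; `strict_vertex = TRUE`
#' additionally requires the gene to be a vertex of a triangle in its
#' terminal module (equivalent here, since the terminal motif *is* a
#' triangle, but kept as an explicit mode).
#'
#' @param tree A `module_tree`.
#' @param hub_count Number of leading hubs to screen (`H`).
#' @param strict_vertex See above; default `FALSE`.
#' @return A data frame of class `fkr_table`, one row per FKR: `gene`,
#'   `fkr_rank` (dense, by level-0 degree), `hub_rank` (dense, among the
#'   screened hubs), `degree`, `terminal_level`, `terminal_module`, plus a
#'   `p_fkr` list-column with each gene's per-level probabilities. Empty
#'   (with a warning) when no branch terminates in a motif.
#' @export
identify_fkr <- function(tree, hub_count, strict_vertex = FALSE) {
  stopifnot(inherits(tree, "module_tree"))
  net <- tree$graph
  hubs <- utils::head(rank_hubs(net), hub_count)
  deg <- igraph::degree(net)[hubs]
  rec <- tree$records
  keep <- logical(length(hubs))
  info <- vector("list", length(hubs))
  for (i in seq_along(hubs)) {
    ids <- branch_modules(tree, hubs[[i]])
    rr <- rec[match(ids, rec$id), ]
    term <- rr[nrow(rr), ]
    ok <- all(rr$qualifies) && term$is_motif
    if (ok && strict_vertex) {
      sub <- igraph::induced_subgraph(net, tree$members[[term$id]])
      ok <- igraph::count_triangles(sub, igraph::V(sub)[hubs[[i]]]) > 0
    }
    keep[i] <- ok
    info[[i]] <- term
  }
  if (!any(keep)) {
    warning("no leading hub reaches motif level: empty FKR set")
  }
  genes <- hubs[keep]
  out <- data.frame(
    gene = genes,
    degree = as.integer(deg[keep]),
    hub_rank = dense_rank_desc(as.numeric(deg))[keep],
    terminal_level = vapply(info[keep], function(t) t$level, integer(1)),
    terminal_module = vapply(info[keep], function(t) t$id, character(1)),
    stringsAsFactors = FALSE)
  out$p_fkr <- lapply(genes, function(g) fkr_probability(tree, g))
  out <- rank_fkr(out)
  class(out) <- c("fkr_table", "data.frame")
  out
}

#' Rank FKR records
#'
#' Dense ranking by level-0 degree, descending: ties share a rank and the
#' next distinct degree takes the following integer.
#'
#' @param records A data frame with a `degree` column (e.g. from
#'   [identify_fkr()]).
#' @return The records ordered by rank, with an `fkr_rank` column.
#' @export
rank_fkr <- function(records) {
  if (nrow(records) == 0) {
    records$fkr_rank <- integer(0)
    return(records)
  }
  records$fkr_rank <- dense_rank_desc(as.numeric(records$degree))
  records[order(records$fkr_rank, records$gene), , drop = FALSE]
}

#' @export
print.fkr_table <- function(x, ...) {
  cat("<fkr_table>", nrow(x), "fundamental key regulator(s)\n")
  print.data.frame(x[, setdiff(names(x), "p_fkr")], row.names = FALSE)
  invisible(x)
}
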