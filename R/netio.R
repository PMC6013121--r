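#' Read a gene-gene interaction network from a file
#'
#' Reads an undirected network from an edge-list, SIF or GraphML file and
#' cleans it: self-loops and duplicate edges are dropped (with a message
#' reporting how many of each), and edge direction, if any was present in the
#' file, is discarded. Node identifiers are treated as opaque gene symbols;
#' no case folding or synonym resolution is performed.
#'
#' Edge-list dialect: whitespace- or tab-separated, the first two columns are
#' used, blank lines and lines starting with `#` are skipped. SIF dialect:
#' `node relation node [node ...]`; a row with several targets expands to one
#' edge per source-target pair; a single-token row declares an isolated node.
#'
#' @param path Path to the network file.
#' @param format One of `"edgelist"`, `"sif"`, `"graphml"`.
#' @param name Label stored on the returned graph (defaults to the file name).
#' @return An undirected simple `igraph` object with character vertex names.
#' @seealso [write_network()], [extract_seed_neighborhood()]
#' @export
read_network <- function(path, format = c("edgelist", "sif", "graphml"),
                         name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read network file: ", path, call. = FALSE)
  }
  g <- switch(format,
    edgelist = read_edgelist_file(path),
    sif = read_sif_file(path),
    graphml = {
      gg <- igraph::read_graph(path, format = "graphml")
      if (igraph::vcount(gg) > 0 && is.null(igraph::V(gg)$name)) {
        igraph::V(gg)$name <- as.character(seq_len(igraph::vcount(gg)))
      }
      gg
    }
  )
  g <- clean_network(g)
  g$name <- name
  g
}

read_edgelist_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  ends <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) < 2) {
      stop("malformed edge-list line ", i, " in ", path,
           ": need at least two columns", call. = FALSE)
    }
    tok[1:2]
  })
  edges_from_pairs(ends)
}

read_sif_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  pairs <- list()
  isolated <- character(0)
  for (i in keep) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) == 1) {
      isolated <- c(isolated, tok)
    } else if (length(tok) == 2) {
      stop("malformed SIF line ", i, " in ", path,
           ": a relation with no target", call. = FALSE)
    } else {
      src <- tok[[1]]
      for (tgt in tok[-(1:2)]) pairs[[length(pairs) + 1L]] <- c(src, tgt)
    }
  }
  g <- edges_from_pairs(pairs)
  extra <- setdiff(isolated, igraph::V(g)$name)
  if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  g
}

edges_from_pairs <- function(pairs) {
  if (length(pairs) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  el <- do.call(rbind, pairs)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Drop self-loops and duplicate edges
#'
#' Idempotent cleaning step applied by [read_network()] and available
#' directly. Reports via `message()` how many self-loops and duplicate edges
#' were removed.
#'
#' @param net An igraph object (possibly with loops/multi-edges).
#' @return The simple undirected graph.
#' @export
clean_network <- function(net) {
  if (igraph::is_directed(net)) net <- igraph::as_undirected(net, mode = "collapse")
  n_loop <- sum(igraph::which_loop(net))
  cleaned <- igraph::simplify(net)
  dup_edges <- (igraph::ecount(net) - n_loop) - igraph::ecount(cleaned)
  if (n_loop > 0) message("dropped ", n_loop, " self-loop(s)")
  if (dup_edges > 0) message("dropped ", dup_edges, " duplicate edge(s)")
  cleaned
}

#' Extract the first-neighbour subnetwork of a seed gene set
#'
#' Induces the subgraph on the seeds together with their direct neighbours,
#' then removes isolated nodes — the construction used to focus a large
#' interactome on a curated disease gene list. By default all edges among the
#' retained nodes are kept (the full induced subgraph); set
#' `seed_incident_only = TRUE` to keep only edges with at least one seed
#' endpoint.
#'
#' @param net An undirected simple igraph network.
#' @param seeds Character vector of seed gene symbols.
#' @param seed_incident_only Keep only seed-incident edges? Default `FALSE`.
#' @return The neighbourhood subnetwork as an igraph object.
#' @export
extract_seed_neighborhood <- function(net, seeds, seed_incident_only = FALSE) {
  check_network(net)
  if (length(seeds) == 0) stop("`seeds` must be non-empty", call. = FALSE)
  present <- intersect(seeds, igraph::V(net)$name)
  missing <- setdiff(seeds, present)
  if (length(missing)) {
    warning(length(missing), " seed(s) not in network: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }
  if (length(present) == 0) {
    stop("none of the seeds are present in the network", call. = FALSE)
  }
  nb <- unique(unlist(lapply(
    igraph::ego(net, order = 1, nodes = present),
    function(v) v$name
  )))
  sub <- igraph::induced_subgraph(net, nb)
  if (seed_incident_only) {
    keep <- unique(unlist(igraph::incident_edges(sub, present)))
    sub <- igraph::subgraph_from_edges(sub, keep, delete.vertices = FALSE)
  }
  iso <- igraph::V(sub)[igraph::degree(sub) == 0]
  if (length(iso)) sub <- igraph::delete_vertices(sub, iso)
  sub
}

#' Write a network to a file
#'
#' Inverse of [read_network()]: round-tripping through any of the three
#' formats preserves the node and edge sets.
#'
#' @param net An undirected simple igraph network.
#' @param path Output path.
#' @param format One of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  check_network(net)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(net, names = TRUE)
  lines <- if (format == "edgelist") {
    if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t") else character(0)
  } else {
    body <- if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(0)
    iso <- igraph::V(net)$name[igraph::degree(net) == 0]
    c(body, iso)
  }
  writeLines(lines, path)
  invisible(path)
}
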