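# Hub knockout experiments: remove the top-n leading hubs (degree ranking on
# the intact network, cumulative) and refit the six degree-indexed power
# laws on each surviving network.

#' Rank nodes by degree (leading hubs first)
#'
#' Degree descending; ties broken lexicographically by gene symbol so the
#' ranking — and everything downstream of it — is deterministic.
#'
#' @param net An undirected simple igraph network.
#' @return Character vector of gene symbols, highest degree first.
#' @export
rank_hubs <- function(net) {
  check_network(net)
  deg <- igraph::degree(net)
  names(deg)[order(-deg, names(deg))]
}

#' Remove the top-n leading hubs
#'
#' Induced subgraph on the non-removed nodes, with nodes isolated by the
#' removal dropped as well (their count is reported via `message()`).
#' `n = 0` returns an identical copy.
#'
#' @param net An undirected simple igraph network.
#' @param n Number of leading hubs to remove (`0 <= n <= N`).
#' @param hubs Optional precomputed hub ranking (defaults to
#'   [rank_hubs()] on `net`).
#' @return The surviving network.
#' @export
remove_top_hubs <- function(net, n, hubs = rank_hubs(net)) {
  check_network(net)
  N <- igraph::vcount(net)
  if (n < 0 || n > N) stop("`n` must be in [0, ", N, "]", call. = FALSE)
  if (n == 0) return(net)
  sub <- igraph::delete_vertices(net, hubs[seq_len(n)])
  iso <- which(igraph::degree(sub) == 0)
  if (length(iso)) {
    message(length(iso), " node(s) isolated by hub removal dropped")
    sub <- igraph::delete_vertices(sub, iso)
  }
  sub
}

# The exponent sextet of one network: gamma (P(k), MLE), alpha (C(k)),
# beta (Cn(k)), epsilon/delta/mu (betweenness/closeness/eigenvector vs k),
# the last five by log-log least squares.
fit_exponent_sextet <- function(net, n_boot_pk = 250, n_boot_curve = 200,
                                seed = NULL) {
  deg <- igraph::degree(net)
  fits <- list()
  fits$gamma <- fit_degree_distribution(deg, n_boot = n_boot_pk,
                                        seed = derive_seed(seed %||% 1, "pk"))
  cl <- clustering_by_degree(net)
  fits$alpha <- tryCatch(
    fit_loglog(cl$curve, n_boot = n_boot_curve,
               seed = derive_seed(seed %||% 1, "ck")),
    error = function(e) NULL)
  fits$beta <- tryCatch(
    fit_loglog(neighborhood_connectivity(net), n_boot = n_boot_curve,
               seed = derive_seed(seed %||% 1, "cnk")),
    error = function(e) NULL)
  cb <- suppressWarnings(betweenness_centrality(net))
  cc <- suppressWarnings(closeness_centrality(net))
  ce <- eigenvector_centrality(net)
  fits$epsilon <- tryCatch(
    fit_loglog(metric_vs_degree(cb, net, "CB(k)"), n_boot = n_boot_curve,
               seed = derive_seed(seed %||% 1, "cb")),
    error = function(e) NULL)
  fits$delta <- tryCatch(
    fit_loglog(metric_vs_degree(cc, net, "CC(k)"), n_boot = n_boot_curve,
               seed = derive_seed(seed %||% 1, "cc")),
    error = function(e) NULL)
  fits$mu <- tryCatch(
    fit_loglog(metric_vs_degree(ce, net, "CE(k)"), n_boot = n_boot_curve,
               seed = derive_seed(seed %||% 1, "ce")),
    error = function(e) NULL)
  fits
}

#' Knockout series: exponent sextet across hub removal sizes
#'
#' For each removal size `n` (0 is always included first), removes the top
#' `n` hubs — ranked once on the intact network and removed cumulatively, so
#' removed sets are nested — and refits all six power laws on the surviving
#' network. Removal sizes leaving fewer than 10 nodes are recorded as not
#' fittable and the series continues.
#'
#' @param net An undirected simple igraph network.
#' @param ns Integer vector of removal sizes (ascending).
#' @param n_boot_pk Bootstrap replicates for the degree-distribution fit.
#' @param n_boot_curve Bootstrap replicates for the curve fits.
#' @param seed RNG seed (fanned out per stage and removal size).
#' @param rerank Re-rank hubs after each removal batch instead of using the
#'   intact-network ranking (default `FALSE`).
#' @return A `knockout_series` object: list with `summary` (one row per n:
#'   exponents, p-values, node/edge counts, fittable flag), `fits` (per-n
#'   list of `power_law_fit` sextets), `removed` (per-n gene vectors).
#' @export
knockout_series <- function(net, ns, n_boot_pk = 250, n_boot_curve = 200,
                            seed = NULL, rerank = FALSE) {
  check_network(net)
  ns <- sort(unique(c(0L, as.integer(ns))))
  hubs <- rank_hubs(net)
  out_fits <- list()
  removed <- list()
  rows <- list()
  cur <- net
  prev_n <- 0L
  for (n in ns) {
    if (rerank) {
      # remove the incremental batch from the current network, re-ranked
      batch <- n - prev_n
      if (batch > 0) {
        cur <- suppressMessages(remove_top_hubs(cur, min(batch, igraph::vcount(cur))))
      }
      surv <- cur
      prev_n <- n
      rem <- setdiff(igraph::V(net)$name, igraph::V(surv)$name)
    } else {
      rem <- hubs[seq_len(n)]
      surv <- suppressMessages(remove_top_hubs(net, n, hubs))
    }
    removed[[as.character(n)]] <- rem
    fittable <- igraph::vcount(surv) >= 10
    fits <- if (fittable) {
      fit_exponent_sextet(surv, n_boot_pk, n_boot_curve,
                          seed = derive_seed(seed %||% 1, paste0("ko", n)))
    } else {
      NULL
    }
    out_fits[[as.character(n)]] <- fits
    grab <- function(f, what) if (is.null(f)) NA_real_ else f[[what]]
    rows[[length(rows) + 1L]] <- data.frame(
      n_removed = n,
      n_nodes = igraph::vcount(surv), n_edges = igraph::ecount(surv),
      fittable = fittable,
      gamma = grab(fits$gamma, "exponent"), gamma_p = grab(fits$gamma, "p_value"),
      alpha = grab(fits$alpha, "exponent"), beta = grab(fits$beta, "exponent"),
      epsilon = grab(fits$epsilon, "exponent"), delta = grab(fits$delta, "exponent"),
      mu = grab(fits$mu, "exponent"))
  }
  structure(list(summary = do.call(rbind, rows), fits = out_fits,
                 removed = removed, rerank = rerank),
            class = "knockout_series")
}

#' @export
print.knockout_series <- function(x, ...) {
  cat("<knockout_series>", nrow(x$summary), "removal sizes",
      if (x$rerank) "(re-ranked)" else "(intact-network ranking)", "\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
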