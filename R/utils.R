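# Internal helpers shared across modules.

# Validate that `net` is the graph type the package works on: an undirected,
# simple igraph object with character vertex names.
check_network <- function(net, arg = "net") {
  if (!igraph::is_igraph(net)) {
    stop("`", arg, "` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(net)) {
    stop("`", arg, "` must be undirected", call. = FALSE)
  }
  if (igraph::vcount(net) > 0 && is.null(igraph::V(net)$name)) {
    stop("`", arg, "` must have named vertices (gene symbols)", call. = FALSE)
  }
  invisible(net)
}

# Evaluate `expr` with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so library functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-stage seed fan-out: a small hash of the stage name folded
# into the master seed, kept strictly below 2^31 so it is a valid R integer.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dense ranking of a numeric vector, largest first: ties share a rank and the
# next distinct value gets the following integer (1,1,2,...).
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}
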