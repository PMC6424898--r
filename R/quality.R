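# Community quality measures: modularity, conductance, CEIL, core score.
#
# All measures are weighted: A_ij is the edge weight and the degree d_i is
# the weighted degree (strength). On unweighted graphs they reduce to the
# usual counting forms.

#' Modularity of a community or a partition
#'
#' Computes `(1/2e) * sum_{i != j} (A_ij - gamma * d_i d_j / 2e) *
#' delta(c(i), c(j))` where `e` is the total edge weight of the whole
#' graph, `d_i` the weighted degree and `delta` equals 1 when both nodes
#' share a community. Self-pairs (`i == j`) are excluded from the null
#' term, so on a d-regular graph with all nodes in one community the score
#' is `sum(d^2)/(2e)^2 = 1/n` (it would be 1 under the convention that
#' includes self-pairs). Given a partition the per-community scores are
#' summed; given a single node set, that community alone is scored against
#' the whole graph.
#'
#' @param g a weighted graph.
#' @param p a partition (named vector, see [as_partition()]) or a single
#'   module (character vector of node names).
#' @param gamma resolution parameter scaling the null term; 1 recovers the
#'   plain score, larger values favour smaller communities.
#' @return a numeric scalar, at most 1.
#' @export
modularity_score <- function(g, p, gamma = 1) {
  .check_graph(g)
  e <- .total_weight(g)
  if (e == 0) stop("graph has no edge weight; modularity undefined", call. = FALSE)
  if (is.null(names(p))) {
    modules <- list(.check_members(g, p))
  } else {
    modules <- partition_to_modules(p)
  }
  d <- igraph::strength(g)
  sum(vapply(modules, function(m) {
    st <- .module_stats(g, m)
    dm <- d[m]
    (2 * st$internal - gamma * (st$volume^2 - sum(dm^2)) / (2 * e)) / (2 * e)
  }, 0))
}

#' Conductance of a community
#'
#' `cut(c) / min(vol(c), vol(complement))`, where the cut is the total
#' weight of edges with exactly one endpoint in `m` and the volume of a
#' set is the sum of the weighted degrees of its members. Lower is better;
#' a whole connected component has conductance 0. Symmetric in `m` and its
#' complement.
#'
#' @param g a weighted graph.
#' @param m a module: character vector of member node names, a non-empty
#'   strict subset of the graph's nodes.
#' @return a numeric scalar in `[0, 1]`.
#' @export
conductance <- function(g, m) {
  .check_graph(g)
  m <- .check_members(g, m)
  if (length(m) >= igraph::vcount(g)) {
    stop("module must be a strict subset of the graph's nodes", call. = FALSE)
  }
  st <- .module_stats(g, m)
  vol_rest <- 2 * .total_weight(g) - st$volume
  denom <- min(st$volume, vol_rest)
  if (denom <= 0) stop("degenerate module: minimum volume is 0", call. = FALSE)
  if (st$cut == 0) return(0)
  st$cut / denom
}

#' CEIL score of a community
#'
#' The product of an internal score (internal density:
#' `W_int / choose(n_c, 2)`, 0 for singletons) and an external score
#' (separability: `W_int / (W_int + cut)`). `W_int` is the intra-module
#' edge weight. For unweighted simple graphs both factors lie in
#' `[0, 1]`; an isolated clique scores 1.
#'
#' @param g a weighted graph.
#' @param m a module (character vector of member node names).
#' @return a numeric scalar; 0 for singleton or edgeless modules.
#' @export
ceil_score <- function(g, m) {
  .check_graph(g)
  m <- .check_members(g, m)
  n_c <- length(m)
  if (n_c < 2) return(0)
  st <- .module_stats(g, m)
  if (st$internal == 0) return(0)
  internal <- st$internal / choose(n_c, 2)
  external <- st$internal / (st$internal + st$cut)
  internal * external
}

#' Per-node core score within a module
#'
#' The ratio of the weight of a node's edges leaving the module to the
#' weight of its edges inside the module. Lower scores mark nodes in the
#' structural core of the module; a node with no outgoing weight scores 0
#' and a node with no internal weight scores `Inf` (so it ranks last and
#' is pruned first).
#'
#' @param g a weighted graph.
#' @param m a module (character vector of member node names).
#' @param node a member of `m` (`core_score`), or omitted to score every
#'   member (`core_scores`).
#' @return `core_score()`: a non-negative scalar or `Inf`;
#'   `core_scores()`: a named vector over the members of `m`.
#' @export
core_score <- function(g, m, node) {
  m <- .check_members(g, m)
  if (!node %in% m) stop("`node` is not a member of the module", call. = FALSE)
  core_scores(g, m)[[node]]
}

#' @rdname core_score
#' @export
core_scores <- function(g, m) {
  .check_graph(g)
  m <- .check_members(g, m)
  d <- igraph::strength(g)[m]
  sub <- igraph::induced_subgraph(g, m)
  w_in <- igraph::strength(sub)[m]
  w_out <- d - w_in
  out <- ifelse(w_out == 0, 0, ifelse(w_in == 0, Inf, w_out / w_in))
  names(out) <- m
  out
}

#' Quality report for a set of modules
#'
#' Scores each module of a partition or cover with size, modularity
#' (single-community form), conductance and CEIL.
#'
#' @param g a weighted graph.
#' @param modules a list of node sets (or a partition, which is split).
#' @return a data.frame with one row per module.
#' @export
score_modules <- function(g, modules) {
  if (!is.list(modules)) modules <- partition_to_modules(modules)
  n_all <- igraph::vcount(g)
  data.frame(
    module = if (is.null(names(modules))) as.character(seq_along(modules)) else names(modules),
    size = lengths(modules),
    modularity = vapply(modules, function(m) modularity_score(g, m), 0),
    conductance = vapply(modules, function(m) {
      if (length(m) >= n_all) NA_real_ else conductance(g, m)
    }, 0),
    ceil = vapply(modules, function(m) ceil_score(g, m), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}
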