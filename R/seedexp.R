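# Seed selection (disease p-values, HITS, spread hubs) and personalized-
# PageRank seed expansion into overlapping modules.

#' Disease seed nodes from a gene-score table
#'
#' Returns the genes present in the graph whose p-value falls below
#' `cutoff` in at least one trait (union across traits). The conventional
#' genome-wide significance cutoffs are `1e-4` and, stricter, `1e-6`.
#'
#' @param scores a numeric matrix of p-values in (0, 1], rows = genes,
#'   columns = traits; `NA` allowed.
#' @param g a weighted graph.
#' @param cutoff p-value threshold in (0, 1).
#' @return a sorted character vector of seed node names (possibly empty,
#'   with a warning), with a `provenance` attribute.
#' @export
disease_seeds <- function(scores, g, cutoff = 1e-4) {
  .check_graph(g)
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must be in (0, 1)", call. = FALSE)
  scores <- as.matrix(scores)
  pass <- rownames(scores)[apply(scores < cutoff, 1, any, na.rm = TRUE)]
  seeds <- sort(intersect(pass, igraph::V(g)$name))
  if (length(seeds) == 0) warning("no gene passes the cutoff", call. = FALSE)
  structure(seeds, provenance = paste0("pvalue_", format(cutoff)))
}

#' HITS hub seeds
#'
#' Power iteration of the hub/authority updates on the (symmetric,
#' weighted) adjacency matrix to tolerance `1e-10`; on an undirected
#' graph the hub score is the principal eigenvector of `A^2`. Returns the
#' `k` nodes of highest hub score, ties broken lexicographically.
#'
#' @param g a weighted graph.
#' @param k number of seeds, `1 <= k <= |V|`.
#' @param tol power-iteration convergence tolerance.
#' @return a character vector of `k` seed node names.
#' @export
hits_seeds <- function(g, k, tol = 1e-10) {
  .check_graph(g)
  n <- igraph::vcount(g)
  if (k < 1 || k > n) stop("`k` must be in [1, |V|]", call. = FALSE)
  nodes <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g)) "weight" else NULL,
                                   sparse = TRUE)
  x <- rep(1, n)
  for (it in seq_len(10000)) {
    a <- as.vector(A %*% x)              # authority update
    h <- as.vector(A %*% a)              # hub update
    nrm <- sqrt(sum(h^2))
    if (nrm == 0) { h <- rep(1 / sqrt(n), n); break }
    h <- h / nrm
    if (max(abs(h - x)) < tol) { x <- h; break }
    x <- h
  }
  structure(nodes[order(-x, nodes)][seq_len(k)], provenance = "hits")
}

#' Spread-hub seeds
#'
#' Greedy selection of high-degree seeds with non-overlapping
#' neighbourhoods: repeatedly take the unmarked node of highest weighted
#' degree (ties lexicographic) as a seed, then mark it and all its
#' neighbours; stop after `k` seeds or when every node is marked (fewer
#' seeds are returned with a warning).
#'
#' @param g a weighted graph.
#' @param k requested number of seeds.
#' @return a character vector of at most `k` seed node names.
#' @export
spread_hub_seeds <- function(g, k) {
  .check_graph(g)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  nodes <- igraph::V(g)$name
  s <- igraph::strength(g)
  ord <- order(-s, nodes)
  marked <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  seeds <- character(0)
  for (i in ord) {
    if (length(seeds) >= k) break
    v <- nodes[i]
    if (marked[[v]]) next
    seeds <- c(seeds, v)
    marked[v] <- TRUE
    nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
    marked[nb] <- TRUE
  }
  if (length(seeds) < k) {
    warning("only ", length(seeds), " spread-hub seeds attainable (requested ", k, ")",
            call. = FALSE)
  }
  structure(seeds, provenance = "spread_hub")
}

#' Approximate personalized PageRank by residual pushes
#'
#' Computes an approximate PPR vector for a unit of probability mass at
#' `seed`, by repeated push operations: a push at node `u` moves
#' `alpha * r_u` of its residual to its score and distributes
#' `(1 - alpha) * r_u` to its neighbours' residuals in proportion to edge
#' weight. Pushing continues until every residual satisfies
#' `r_u < eps * d_u`. Mass is conserved throughout:
#' `sum(score) + sum(residual) == 1`. A degree-0 node absorbs its
#' residual into its score, so an isolated seed ends with score 1.
#'
#' @param g a weighted graph.
#' @param seed a node name.
#' @param alpha teleport probability in (0, 1) (default 0.85).
#' @param eps push tolerance (default 1e-5).
#' @return a list with named numeric vectors `score` and `residual`, and
#'   the `alpha` and `eps` used.
#' @export
ppr <- function(g, seed, alpha = 0.85, eps = 1e-5) {
  .check_graph(g)
  nodes <- igraph::V(g)$name
  if (!seed %in% nodes) stop("`seed` not in graph", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  n <- length(nodes)
  d <- igraph::strength(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  inc <- igraph::as_adj_edge_list(g, mode = "all")
  ew <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0)
  p <- numeric(n); r <- numeric(n)
  si <- match(seed, nodes)
  r[si] <- 1
  queue <- si
  inq <- logical(n); inq[si] <- TRUE
  while (length(queue) > 0) {
    u <- queue[[1]]; queue <- queue[-1]; inq[u] <- FALSE
    ru <- r[u]
    if (d[u] == 0) { p[u] <- p[u] + ru; r[u] <- 0; next }
    if (ru < eps * d[u]) next
    r[u] <- 0
    p[u] <- p[u] + alpha * ru
    vs <- as.integer(adj[[u]])
    w <- ew[as.integer(inc[[u]])]
    r[vs] <- r[vs] + (1 - alpha) * ru * w / d[u]
    push <- vs[r[vs] >= eps * d[vs] & !inq[vs]]
    if (length(push) > 0) { queue <- c(queue, push); inq[push] <- TRUE }
  }
  list(score = stats::setNames(p, nodes), residual = stats::setNames(r, nodes),
       alpha = alpha, eps = eps)
}

#' Expand a seed node into a module
#'
#' Ranks the nodes reachable from the seed by degree-normalized PPR score
#' (descending; `normalize = FALSE` ranks by the raw score) and grows a
#' candidate set from the seed one node at a time up to `max_size`,
#' recording the single-community modularity ([modularity_score()],
#' normalized by the whole graph's `2e`) after each addition. The prefix
#' of maximum modularity among those of size at least `min_size` is the
#' module; the seed is always a member. Seeds for which no prefix reaches
#' `min_size` are rejected (`NULL` with a warning).
#'
#' @param g a weighted graph.
#' @param seed a node name.
#' @param alpha,eps PPR parameters, see [ppr()].
#' @param max_size,min_size module size bounds (defaults 100 and 3, the
#'   disease-module size range).
#' @param normalize rank by `score/degree` (default) or raw score.
#' @return a character vector of module members, or `NULL` if rejected.
#' @export
expand_seed <- function(g, seed, alpha = 0.85, eps = 1e-5, max_size = 100,
                        min_size = 3, normalize = TRUE) {
  .check_graph(g)
  if (min_size < 2 || min_size > max_size) stop("need 2 <= min_size <= max_size", call. = FALSE)
  pv <- ppr(g, seed, alpha = alpha, eps = eps)
  d <- igraph::strength(g)
  sc <- pv$score
  cand <- setdiff(names(sc)[sc > 0 & d > 0], seed)
  if (length(cand) < min_size - 1) {
    warning("seed ", seed, " rejected: neighborhood too small", call. = FALSE)
    return(NULL)
  }
  rank_key <- if (normalize) sc[cand] / d[cand] else sc[cand]
  cand <- cand[order(-rank_key, cand)]
  cand <- cand[seq_len(min(length(cand), max_size - 1))]
  # incremental single-community modularity over growing prefixes
  e2 <- 2 * .total_weight(g)
  nodes <- c(seed, cand)
  nbrs <- igraph::as_adj_list(g, mode = "all")
  inc <- igraph::as_adj_edge_list(g, mode = "all")
  ew <- igraph::E(g)$weight
  name_idx <- stats::setNames(seq_along(igraph::V(g)$name), igraph::V(g)$name)
  inset <- logical(igraph::vcount(g))
  W <- 0; vol <- 0; sumd2 <- 0
  q <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    u <- name_idx[[nodes[i]]]
    vs <- as.integer(nbrs[[u]])
    w <- ew[as.integer(inc[[u]])]
    W <- W + sum(w[inset[vs]])
    vol <- vol + d[u]
    sumd2 <- sumd2 + d[u]^2
    inset[u] <- TRUE
    q[i] <- (2 * W - (vol^2 - sumd2) / e2) / e2
  }
  ok <- seq_along(nodes) >= min_size
  if (!any(ok)) {
    warning("seed ", seed, " rejected: no prefix reaches min_size", call. = FALSE)
    return(NULL)
  }
  best <- which(ok)[which.max(q[ok])]
  nodes[seq_len(best)]
}

#' Expand every seed of a seed set
#'
#' Runs [expand_seed()] for each seed and assembles the accepted modules
#' into a cover; modules with identical node sets are deduplicated.
#'
#' @param g a weighted graph.
#' @param seeds a non-empty character vector of seed node names.
#' @inheritParams expand_seed
#' @return a list with elements `cover` (named list of modules, labels
#'   `M1`, `M2`, ...), `seed_map` (named character, seed -> module label)
#'   and `rejected` (character vector of rejected seeds).
#' @export
expand_all <- function(g, seeds, alpha = 0.85, eps = 1e-5, max_size = 100,
                       min_size = 3, normalize = TRUE) {
  if (length(seeds) == 0) stop("`seeds` must be non-empty", call. = FALSE)
  cover <- list()
  keys <- character(0)
  seed_map <- character(0)
  rejected <- character(0)
  for (s in seeds) {
    m <- expand_seed(g, s, alpha = alpha, eps = eps, max_size = max_size,
                     min_size = min_size, normalize = normalize)
    if (is.null(m)) { rejected <- c(rejected, s); next }
    key <- paste(sort(m), collapse = "\r")
    hit <- match(key, keys)
    if (is.na(hit)) {
      keys <- c(keys, key)
      cover[[paste0("M", length(keys))]] <- m
      hit <- length(keys)
    }
    seed_map[[s]] <- paste0("M", hit)
  }
  if (length(cover) == 0) warning("all seeds rejected; empty cover", call. = FALSE)
  list(cover = cover, seed_map = seed_map, rejected = rejected)
}
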