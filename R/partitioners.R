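# Baseline non-overlapping partitioners: resistance-parameterized Louvain,
# Markov clustering (MCL), and CEIL-objective local moving.

#' Louvain modularity maximization with a resistance parameter
#'
#' Multilevel greedy modularity maximization (Louvain), with the
#' resistance parameter `R` acting as the resolution multiplier on the
#' null term: the objective is `sum_{i != j} (A_ij - R d_i d_j / 2e)
#' delta`. Smaller `R` yields larger modules. The node visit order is
#' randomized, so a seed makes the result reproducible; disconnected
#' components are clustered independently.
#'
#' @param g a non-empty weighted graph.
#' @param resistance resolution multiplier, conventionally in `[0.1, 1]`
#'   (default 0.1).
#' @param seed optional integer seed for the RNG.
#' @return a named integer partition (labels `1..k`).
#' @export
louvain_partition <- function(g, resistance = 0.1, seed = NULL) {
  .check_graph(g)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  if (resistance <= 0) stop("`resistance` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (igraph::ecount(g) == 0) {
    p <- seq_len(igraph::vcount(g))
    names(p) <- igraph::V(g)$name
    return(p)
  }
  cl <- igraph::cluster_louvain(g, resolution = resistance)
  p <- igraph::membership(cl)
  as_partition(stats::setNames(as.integer(p), igraph::V(g)$name))
}

#' Markov clustering (MCL)
#'
#' Random-walk flow clustering: the column-stochastic transition matrix
#' (with self-loops of weight 1 added) is alternately *expanded* (matrix
#' power `expansion`) and *inflated* (elementwise power `inflation`
#' followed by column renormalization) until the maximum entrywise change
#' falls below `tol`. Entries below `prune` are dropped each iteration to
#' keep the matrix sparse. Clusters are read off as the weakly connected
#' components of the nonzero pattern of the limit matrix, which also
#' resolves nodes attracted by several attractors to a single cluster.
#'
#' @param g a non-empty weighted graph.
#' @param inflation inflation exponent `I > 1`; the conventional grid is
#'   `2..9`.
#' @param expansion matrix-power exponent (conventionally fixed at 2).
#' @param max_iter iteration cap; non-convergence returns the current
#'   interpretation with a warning.
#' @param tol convergence tolerance on the maximum entry change.
#' @param prune per-iteration pruning threshold.
#' @return a named integer partition.
#' @export
mcl_partition <- function(g, inflation = 2, expansion = 2, max_iter = 100,
                          tol = 1e-6, prune = 1e-8) {
  .check_graph(g)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  if (inflation <= 1) stop("`inflation` must be > 1", call. = FALSE)
  if (expansion < 2) stop("`expansion` must be >= 2", call. = FALSE)
  A <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g)) "weight" else NULL,
                                   sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix") + Matrix::Diagonal(n)
  normalize <- function(M) M %*% Matrix::Diagonal(x = 1 / Matrix::colSums(M))
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (k in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp
    Minf@x <- Minf@x^inflation
    Minf <- normalize(Minf)
    Minf <- Matrix::drop0(Minf * (abs(Minf) >= prune))
    Minf <- normalize(Minf)
    if (max(abs(Minf - M)) < tol) {
      M <- Minf
      converged <- TRUE
      break
    }
    M <- Minf
  }
  if (!converged) warning("MCL did not converge in ", max_iter, " iterations",
                          call. = FALSE)
  pat <- M + Matrix::t(M)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    pat, mode = "undirected", weighted = TRUE, diag = FALSE))
  as_partition(stats::setNames(comp$membership, igraph::V(g)$name))
}

# CEIL value of a community from its cached stats.
.ceil_from_stats <- function(n_c, w_int, vol) {
  if (n_c < 2 || w_int <= 0) return(0)
  (w_int / (n_c * (n_c - 1) / 2)) * (w_int / (vol - w_int))
}

#' CEIL-objective clustering
#'
#' Greedy local moving (Louvain-style sweeps over the nodes, without
#' aggregation) maximizing the size-weighted network CEIL objective
#' `sum_c (n_c / n) * CEIL(c)`. Starting from singletons, each sweep
#' offers every node a move to a neighbouring community and accepts the
#' move with the largest strictly positive objective gain, until a full
#' sweep moves no node. The method has no hyperparameter.
#'
#' @param g a non-empty weighted graph.
#' @param max_sweeps safety cap on the number of sweeps.
#' @return a named integer partition.
#' @export
ceil_partition <- function(g, max_sweeps = 100) {
  .check_graph(g)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  nodes <- igraph::V(g)$name
  d <- igraph::strength(g)
  el <- igraph::as_data_frame(g, what = "edges")
  # adjacency lists by integer index
  ai <- match(el$from, nodes); bi <- match(el$to, nodes)
  nbr <- vector("list", n); wts <- vector("list", n)
  for (i in seq_len(n)) { nbr[[i]] <- integer(0); wts[[i]] <- numeric(0) }
  ord <- c(ai, bi); oth <- c(bi, ai); ww <- c(el$weight, el$weight)
  sp <- split(seq_along(ord), ord)
  for (k in names(sp)) {
    i <- as.integer(k)
    nbr[[i]] <- oth[sp[[k]]]
    wts[[i]] <- ww[sp[[k]]]
  }
  comm <- seq_len(n)                     # membership
  c_n <- rep(1L, n)                      # community sizes
  c_w <- rep(0, n)                       # internal weights
  c_v <- d                               # volumes
  contrib <- function(size, w_int, vol) (size / n) * .ceil_from_stats(size, w_int, vol)
  visit <- order(nodes)                  # deterministic sweep order
  for (sweep in seq_len(max_sweeps)) {
    moved <- 0L
    for (i in visit) {
      ci <- comm[i]
      if (length(nbr[[i]]) == 0) next
      # weight from i to each neighbouring community
      w_to <- tapply(wts[[i]], comm[nbr[[i]]], sum)
      cand <- as.integer(names(w_to))
      base_src <- contrib(c_n[ci], c_w[ci], c_v[ci])
      w_i_ci <- if (as.character(ci) %in% names(w_to)) w_to[[as.character(ci)]] else 0
      src_rm <- contrib(c_n[ci] - 1L, c_w[ci] - w_i_ci, c_v[ci] - d[i])
      best_gain <- 0; best_c <- ci
      for (cj in cand) {
        if (cj == ci) next
        w_i_cj <- w_to[[as.character(cj)]]
        gain <- (src_rm - base_src) +
          (contrib(c_n[cj] + 1L, c_w[cj] + w_i_cj, c_v[cj] + d[i]) -
             contrib(c_n[cj], c_w[cj], c_v[cj]))
        if (gain > best_gain + 1e-12) { best_gain <- gain; best_c <- cj }
      }
      if (best_c != ci) {
        w_i_cj <- w_to[[as.character(best_c)]]
        c_n[ci] <- c_n[ci] - 1L; c_w[ci] <- c_w[ci] - w_i_ci; c_v[ci] <- c_v[ci] - d[i]
        c_n[best_c] <- c_n[best_c] + 1L
        c_w[best_c] <- c_w[best_c] + w_i_cj
        c_v[best_c] <- c_v[best_c] + d[i]
        comm[i] <- best_c
        moved <- moved + 1L
      }
    }
    if (moved == 0L) break
  }
  as_partition(stats::setNames(comm, nodes))
}

#' Size-weighted network CEIL objective of a partition
#'
#' @param g a weighted graph.
#' @param p a partition.
#' @return `sum_c (n_c / n) * CEIL(c)`.
#' @export
ceil_objective <- function(g, p) {
  p <- .validate_partition(g, p)
  n <- igraph::vcount(g)
  sum(vapply(partition_to_modules(p), function(m) {
    st <- .module_stats(g, m)
    (length(m) / n) * .ceil_from_stats(length(m), st$internal, st$volume)
  }, 0))
}
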