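# Synthetic benchmarks: planted (optionally overlapping) weighted
# networks and synthetic GWAS gene-score tables, so every pipeline stage
# is testable without external data.

.make_block_edges <- function(block, p_in, p_out, w_in, w_out) {
  n <- length(block)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- block[pr[, 1]] == block[pr[, 2]]
  p_in_blk <- rep_len(p_in, max(block))           # per-block density allowed
  prob <- ifelse(same, p_in_blk[block[pr[, 1]]], p_out)
  keep <- stats::runif(nrow(pr)) < prob
  pr <- pr[keep, , drop = FALSE]; same <- same[keep]
  w <- numeric(nrow(pr))
  w[same] <- stats::runif(sum(same), w_in[1], w_in[2])
  w[!same] <- stats::runif(sum(!same), w_out[1], w_out[2])
  list(pairs = pr, weight = w)
}

#' Planted-partition benchmark graph
#'
#' Generates a weighted planted-partition graph: node pairs within a
#' block are joined independently with probability `p_in`, pairs across
#' blocks with probability `p_out`. Within-block weights are drawn from
#' `Uniform(w_in[1], w_in[2])` (default 0.6-1) and between-block weights
#' from `Uniform(w_out[1], w_out[2])` (default 0.1-0.5), mimicking the
#' confidence-score semantics of interaction networks where true
#' interactions carry high confidence.
#'
#' @param sizes block sizes (each at least 3).
#' @param p_in,p_out within/between-block edge probabilities,
#'   `p_in > p_out >= 0`; `p_in` may be a vector (one density per block)
#'   to plant blocks of unequal structural strength.
#' @param w_in,w_out weight ranges (length-2 numeric).
#' @param seed RNG seed.
#' @return a `planted_benchmark` list: `graph` (igraph), `truth` (named
#'   integer partition), `modules` (the truth as a list), `config`.
#' @export
planted_partition <- function(sizes, p_in = 0.3, p_out = 0.01,
                              w_in = c(0.6, 1), w_out = c(0.1, 0.5),
                              seed = NULL) {
  if (any(sizes < 3)) stop("every block needs >= 3 nodes", call. = FALSE)
  if (!(all(p_in > p_out) && p_out >= 0)) stop("need p_in > p_out >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- sum(sizes)
  nodes <- sprintf("g%0*d", nchar(n), seq_len(n))
  block <- rep(seq_along(sizes), sizes)
  be <- .make_block_edges(block, p_in, p_out, w_in, w_out)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes[be$pairs[, 1]], to = nodes[be$pairs[, 2]],
               weight = be$weight, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  truth <- stats::setNames(block, nodes)
  structure(list(graph = g, truth = truth,
                 modules = partition_to_modules(truth),
                 config = list(sizes = sizes, p_in = p_in, p_out = p_out,
                               w_in = w_in, w_out = w_out, seed = seed)),
            class = "planted_benchmark")
}

#' Planted benchmark with overlapping modules
#'
#' As [planted_partition()], plus `n_overlap` designated overlap nodes per
#' adjacent block pair: each overlap node is wired with probability
#' `p_in` into the members of both blocks of its pair (and with `p_out`
#' elsewhere) and belongs to exactly two truth modules, so the truth is a
#' cover. With `n_overlap = 0` no overlap nodes are created and the truth
#' cover is the plain block partition.
#'
#' @inheritParams planted_partition
#' @param n_overlap overlap nodes per adjacent block pair (`>= 0`; must
#'   not exceed the smallest block size).
#' @return a `planted_benchmark` list with `truth_cover` (named list of
#'   modules with shared members) in place of a partition truth.
#' @export
overlapping_benchmark <- function(sizes, p_in = 0.3, p_out = 0.01,
                                  n_overlap = 2, w_in = c(0.6, 1),
                                  w_out = c(0.1, 0.5), seed = NULL) {
  if (n_overlap < 0) stop("`n_overlap` must be >= 0", call. = FALSE)
  if (n_overlap > min(sizes)) stop("overlap exceeds block size", call. = FALSE)
  if (any(sizes < 3)) stop("every block needs >= 3 nodes", call. = FALSE)
  if (!(p_in > p_out && p_out >= 0)) stop("need p_in > p_out >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- sum(sizes)
  nodes <- sprintf("g%0*d", nchar(n), seq_len(n))
  block <- rep(seq_along(sizes), sizes)
  be <- .make_block_edges(block, p_in, p_out, w_in, w_out)
  edges <- data.frame(from = nodes[be$pairs[, 1]], to = nodes[be$pairs[, 2]],
                      weight = be$weight, stringsAsFactors = FALSE)
  k <- length(sizes)
  cover <- partition_to_modules(stats::setNames(block, nodes))
  names(cover) <- as.character(seq_len(k))
  onodes <- character(0)
  if (n_overlap > 0 && k >= 2) {
    for (b in seq_len(k - 1)) {
      for (j in seq_len(n_overlap)) {
        v <- sprintf("o%d_%d_%d", b, b + 1, j)
        onodes <- c(onodes, v)
        for (tb in c(b, b + 1)) {
          mem <- nodes[block == tb]
          hit <- mem[stats::runif(length(mem)) < p_in]
          if (length(hit) > 0) {
            edges <- rbind(edges, data.frame(
              from = v, to = hit,
              weight = stats::runif(length(hit), w_in[1], w_in[2]),
              stringsAsFactors = FALSE))
          }
          cover[[as.character(tb)]] <- c(cover[[as.character(tb)]], v)
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = data.frame(name = c(nodes, onodes)))
  structure(list(graph = g, truth_cover = cover,
                 config = list(sizes = sizes, p_in = p_in, p_out = p_out,
                               n_overlap = n_overlap, w_in = w_in,
                               w_out = w_out, seed = seed)),
            class = "planted_benchmark")
}

#' Synthetic GWAS gene-score table for a planted benchmark
#'
#' Emulates a panel of GWAS gene-score datasets at toy scale: for each
#' trait, the genes of that trait's causal truth modules receive p-values
#' from `Beta(a, 1)` (CDF `x^a`, so with the default effect `a = 0.1` a
#' causal gene passes the `1e-4` cutoff with probability
#' `(1e-4)^0.1 ~= 0.398`); every other cell is `Uniform(0, 1)`.
#'
#' @param bench a `planted_benchmark`.
#' @param n_traits number of traits (columns).
#' @param causal named list trait name -> character vector of causal truth
#'   module labels; by default trait `t` is causal for module
#'   `((t - 1) %% k) + 1`.
#' @param a causal Beta shape, `0 < a < 1` (smaller = stronger signal).
#' @param seed RNG seed.
#' @return a genes x traits matrix of p-values with a `causal` attribute.
#' @export
synth_gwas <- function(bench, n_traits = 3, causal = NULL, a = 0.1, seed = NULL) {
  if (a <= 0 || a >= 1) stop("`a` must be in (0, 1)", call. = FALSE)
  if (n_traits < 1) stop("`n_traits` must be >= 1", call. = FALSE)
  modules <- if (!is.null(bench$truth_cover)) bench$truth_cover else bench$modules
  if (!is.null(seed)) set.seed(seed)
  genes <- igraph::V(bench$graph)$name
  traits <- paste0("trait", seq_len(n_traits))
  if (is.null(causal)) {
    causal <- stats::setNames(
      as.list(names(modules)[(seq_len(n_traits) - 1) %% length(modules) + 1]),
      traits)
  }
  bad <- setdiff(unlist(causal), names(modules))
  if (length(bad) > 0) stop("causal module not in truth: ", bad[1], call. = FALSE)
  m <- matrix(stats::runif(length(genes) * n_traits), nrow = length(genes),
              dimnames = list(genes, traits))
  for (tr in names(causal)) {
    cg <- unique(unlist(modules[causal[[tr]]]))
    m[cg, tr] <- stats::runif(length(cg))^(1 / a)   # Beta(a, 1)
  }
  attr(m, "causal") <- causal
  m
}
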