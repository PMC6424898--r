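# Graph and module-file I/O and preprocessing.

#' Read a weighted edge list
#'
#' Reads a whitespace/TAB-delimited edge list with at least three columns
#' per line: `node_a node_b weight`. Lines starting with `#` and blank
#' lines are ignored. The result is always an undirected, simple, weighted
#' graph: self-loop lines are dropped with a warning and duplicate
#' unordered pairs are either an error (conflicting weights with
#' `symmetrize = FALSE`) or collapsed to the maximum weight
#' (`symmetrize = TRUE`, the treatment for directed inputs such as
#' signaling networks).
#'
#' @param path path to the edge-list file.
#' @param symmetrize if `TRUE`, repeated unordered pairs (e.g. both
#'   directions of a directed edge) are collapsed keeping the maximum
#'   weight; if `FALSE`, repeated pairs with conflicting weights raise an
#'   error.
#' @return an undirected weighted [igraph::igraph] with named vertices.
#' @export
read_weighted_edgelist <- function(path, symmetrize = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- idx[which(nf < 3)[1]]
    stop("parse error at line ", bad, ": fewer than 3 columns", call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(w)) {
    bad <- idx[which(is.na(w))[1]]
    stop("parse error at line ", bad, ": non-numeric weight", call. = FALSE)
  }
  if (any(w <= 0)) {
    bad <- idx[which(w <= 0)[1]]
    stop("parse error at line ", bad, ": weight must be > 0", call. = FALSE)
  }
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop line(s) dropped", call. = FALSE)
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    if (symmetrize) {
      w <- tapply(w, key, max)
      pair <- strsplit(names(w), "\r", fixed = TRUE)
      lo <- vapply(pair, `[[`, "", 1L)
      hi <- vapply(pair, `[[`, "", 2L)
      w <- as.numeric(w)
    } else {
      rng <- tapply(w, key, function(x) diff(range(x)))
      if (any(rng > 0)) {
        stop("duplicate edge with conflicting weights: ",
             sub("\r", "--", names(rng)[which(rng > 0)[1]]),
             " (set symmetrize = TRUE to keep the maximum)", call. = FALSE)
      }
      first <- !duplicated(key)
      lo <- lo[first]; hi <- hi[first]; w <- w[first]
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, weight = w, stringsAsFactors = FALSE),
    directed = FALSE)
  .check_graph(g)
}

#' Sparsify a weighted graph by a global weight threshold
#'
#' Biological networks are noisy; removing low-confidence edges both
#' speeds clustering up and improves it. Three thresholding modes are
#' supported, all computed from the full weight distribution:
#' `mean_minus_ksd` keeps `w >= mu - k*sigma` (the default, with `k = 2`,
#' i.e. removing edges more than two standard deviations below the mean),
#' `mean_plus_ksd` keeps `w >= mu + k*sigma`, and `quantile` keeps
#' `w >= quantile(w, q)`. `sigma` is the population standard deviation of
#' the edge weights. The node set is preserved, so sparsification can
#' create isolated nodes.
#'
#' @param g a weighted graph.
#' @param mode thresholding mode, see above.
#' @param k number of standard deviations (`mean_*` modes), `k >= 0`.
#' @param q quantile in (0, 1) (`quantile` mode).
#' @return the thresholded graph (same node set).
#' @export
sparsify <- function(g, mode = c("mean_minus_ksd", "mean_plus_ksd", "quantile"),
                     k = 2, q = NULL) {
  mode <- match.arg(mode)
  .check_graph(g)
  if (igraph::ecount(g) == 0) return(g)
  w <- igraph::E(g)$weight
  thr <- switch(mode,
    mean_minus_ksd = {
      stopifnot(k >= 0)
      mean(w) - k * sqrt(mean((w - mean(w))^2))
    },
    mean_plus_ksd = {
      stopifnot(k >= 0)
      mean(w) + k * sqrt(mean((w - mean(w))^2))
    },
    quantile = {
      if (is.null(q) || q <= 0 || q >= 1) stop("`q` must be in (0,1)", call. = FALSE)
      stats::quantile(w, q, names = FALSE)
    })
  drop <- which(w < thr)
  message(sprintf("sparsify: removed %d/%d edges (%.1f%%), threshold %.4g",
                  length(drop), length(w), 100 * length(drop) / length(w), thr))
  igraph::delete_edges(g, drop)
}

#' Density of a simple undirected graph
#'
#' @param n_nodes number of nodes (`>= 2`).
#' @param n_edges number of edges.
#' @return `2 * n_edges / (n_nodes * (n_nodes - 1))`.
#' @export
graph_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("`n_nodes` must be >= 2", call. = FALSE)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Write / read module files
#'
#' The module file format is one module per line: an integer module id, a
#' TAB, then the TAB-separated node identifiers. `read_modules()` inverts
#' `write_modules()` losslessly.
#'
#' @param modules a list of non-empty character vectors (node sets).
#' @param path output (input) file path.
#' @return `write_modules()` returns `path` invisibly; `read_modules()`
#'   returns a list of character vectors named by module id.
#' @export
write_modules <- function(modules, path) {
  if (any(lengths(modules) == 0)) stop("empty module", call. = FALSE)
  lines <- vapply(seq_along(modules), function(i) {
    paste(c(i, as.character(modules[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) stop("malformed module file", call. = FALSE)
  out <- lapply(fields, function(x) x[-1])
  names(out) <- vapply(fields, `[[`, "", 1L)
  out
}

#' Largest connected component of an induced subgraph
#'
#' Induces the subgraph on `genes` (unknown genes are dropped with a
#' warning) and returns the node set of its largest connected component.
#' Size ties are broken in favour of the component containing the
#' lexicographically smallest node.
#'
#' @param g a weighted graph.
#' @param genes a character vector of node identifiers.
#' @return a sorted character vector, the LCC node set.
#' @export
largest_connected_component <- function(g, genes) {
  .check_graph(g)
  genes <- unique(as.character(genes))
  known <- intersect(genes, igraph::V(g)$name)
  if (length(known) < length(genes)) {
    warning(length(genes) - length(known), " gene(s) not in graph, dropped",
            call. = FALSE)
  }
  if (length(known) == 0) stop("no genes left after filtering", call. = FALSE)
  sub <- igraph::induced_subgraph(g, known)
  comp <- igraph::components(sub)
  best <- max(comp$csize)
  cand <- which(comp$csize == best)
  sets <- lapply(cand, function(ci) sort(igraph::V(sub)$name[comp$membership == ci]))
  sets[[order(vapply(sets, `[[`, "", 1L))[1]]]
}
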