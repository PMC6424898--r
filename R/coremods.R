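# Core-module identification frameworks: consensus ensembles, perturbation
# consensus, reclustering of oversized modules, and minimum-outgoing cores.

#' Consensus network from a set of base clusterings
#'
#' Each node carries an assignment vector: its community label in each of
#' the `r` base clusterings, qualified by the clustering index (labels
#' from different clusterings never match). For every node pair the
#' Jaccard similarity of the two assignment vectors is computed: with `a`
#' agreements out of `r` clusterings this is `a / (2r - a)` (the
#' `"simple"` variant uses the matching fraction `a / r`). Pairs with
#' similarity strictly above `threshold` are linked, the similarity
#' becoming the edge weight. Similarity is 1 exactly when two nodes
#' co-occur in every base clustering.
#'
#' @param assignments a list of partitions (named vectors over the same
#'   node set) or a node-by-clustering label matrix with rownames.
#' @param threshold linking threshold (default 0.5).
#' @param method `"qualified"` Jaccard `a/(2r-a)` (default) or `"simple"`
#'   matching fraction `a/r`.
#' @return an undirected weighted igraph over all nodes; nodes whose every
#'   similarity falls at or below the threshold are isolated.
#' @export
consensus_network <- function(assignments, threshold = 0.5,
                              method = c("qualified", "simple")) {
  method <- match.arg(method)
  if (is.list(assignments)) {
    if (length(assignments) == 0) stop("need at least one base clustering", call. = FALSE)
    nodes <- names(assignments[[1]])
    lab <- vapply(assignments, function(p) as.integer(p[nodes]), integer(length(nodes)))
    lab <- matrix(lab, nrow = length(nodes), dimnames = list(nodes, NULL))
  } else {
    lab <- as.matrix(assignments)
    if (is.null(rownames(lab))) stop("assignment matrix needs rownames", call. = FALSE)
    nodes <- rownames(lab)
  }
  r <- ncol(lab)
  if (r == 0) stop("need at least one base clustering", call. = FALSE)
  n <- nrow(lab)
  # count pairwise agreements by enumerating co-membership pairs per clustering
  ii <- integer(0); jj <- integer(0)
  for (q in seq_len(r)) {
    for (idx in split(seq_len(n), lab[, q])) {
      if (length(idx) < 2) next
      pr <- utils::combn(idx, 2)
      ii <- c(ii, pr[1, ]); jj <- c(jj, pr[2, ])
    }
  }
  if (length(ii) > 0) {
    agree <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
    trip <- Matrix::summary(agree)
    a <- trip$x
    sim <- if (method == "qualified") a / (2 * r - a) else a / r
    keep <- sim > threshold
    edges <- data.frame(from = nodes[trip$i[keep]], to = nodes[trip$j[keep]],
                        weight = sim[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

# Run one base-clustering config; cfg is list(method=..., <params>).
.run_base <- function(g, cfg) {
  method <- cfg$method
  switch(method,
    louvain = louvain_partition(g, resistance = cfg$resistance %||% 0.1),
    mcl = mcl_partition(g, inflation = cfg$inflation %||% 2),
    ceil = ceil_partition(g),
    stop("unknown base method: ", method, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble clustering via Jaccard consensus
#'
#' Runs every base clustering config on the graph, builds the consensus
#' network of the resulting assignment vectors ([consensus_network()]),
#' and clusters the consensus network with Louvain. Nodes isolated in the
#' consensus network (never reliably co-clustered) become singletons.
#'
#' By default the consensus uses the majority co-association form
#' (`"simple"`: link pairs co-clustered in more than half the base runs).
#' The qualified-Jaccard form `a/(2r - a)` at threshold 0.5 demands
#' agreement in more than two thirds of the runs, which a heterogeneous
#' base set (MCL at high inflation and CEIL legitimately shatter sparse
#' communities) cannot deliver even when every Louvain run agrees; the
#' majority form keeps the consensus usable with the full baseline grid.
#' Set `consensus = "qualified"` for the stricter variant.
#'
#' @param g a weighted graph.
#' @param base_runs non-empty list of base configs, each a list with
#'   `method` in `louvain`/`mcl`/`ceil` plus its hyperparameters; see
#'   [baseline_runs()] for the full default grid.
#' @param threshold consensus linking threshold.
#' @param resistance resistance for the final Louvain step.
#' @param seed optional RNG seed (passed to the final Louvain step).
#' @param consensus similarity form, see [consensus_network()].
#' @return a named integer partition over all nodes of `g`.
#' @export
ensemble_cluster <- function(g, base_runs, threshold = 0.5, resistance = 0.1,
                             seed = NULL, consensus = c("simple", "qualified")) {
  .check_graph(g)
  consensus <- match.arg(consensus)
  if (length(base_runs) == 0) stop("`base_runs` must be non-empty", call. = FALSE)
  parts <- lapply(base_runs, function(cfg) .run_base(g, cfg))
  cons <- consensus_network(parts, threshold = threshold, method = consensus)
  .cluster_consensus(cons, resistance, seed)
}

# Louvain on a consensus network; isolated nodes become singletons.
.cluster_consensus <- function(cons, resistance, seed) {
  deg <- igraph::degree(cons)
  linked <- names(deg)[deg > 0]
  iso <- names(deg)[deg == 0]
  if (length(linked) > 0) {
    sub <- igraph::induced_subgraph(cons, linked)
    p <- louvain_partition(sub, resistance = resistance, seed = seed)
  } else {
    p <- stats::setNames(integer(0), character(0))
  }
  if (length(iso) > 0) {
    p <- c(p, stats::setNames(max(p, 0L) + seq_along(iso), iso))
  }
  as_partition(p[sort(names(p))])
}

#' Perturbation-consensus clustering
#'
#' Identifies modules robust to network noise: the graph is perturbed
#' `iterations` times by dropping `floor(drop_frac * |E|)` edges uniformly
#' at random, each perturbed copy is clustered with Louvain (resistance
#' 0.1), and the resulting partitions are combined through the Jaccard
#' consensus network, which is finally clustered with Louvain again.
#'
#' @param g a weighted graph with at least one edge.
#' @param drop_frac fraction of edges dropped per perturbation (default
#'   0.01, i.e. 1%).
#' @param iterations number of perturbed copies (default 100).
#' @param resistance resistance for the per-copy and final Louvain steps.
#' @param threshold consensus linking threshold.
#' @param seed RNG seed governing all edge drops.
#' @return a named integer partition.
#' @export
perturbation_cluster <- function(g, drop_frac = 0.01, iterations = 100,
                                 resistance = 0.1, threshold = 0.5, seed = NULL) {
  .check_graph(g)
  ne <- igraph::ecount(g)
  if (ne < 1) stop("graph has no edges", call. = FALSE)
  if (drop_frac < 0 || drop_frac >= 1) stop("`drop_frac` must be in [0, 1)", call. = FALSE)
  if (iterations < 1) stop("`iterations` must be >= 1", call. = FALSE)
  n_drop <- floor(drop_frac * ne)
  if (n_drop >= ne) stop("perturbation would drop every edge", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(seq_len(iterations), function(i) {
    gp <- if (n_drop > 0) igraph::delete_edges(g, sample.int(ne, n_drop)) else g
    louvain_partition(gp, resistance = resistance)
  })
  if (iterations == 1) return(as_partition(parts[[1]]))
  cons <- consensus_network(parts, threshold = threshold)
  .cluster_consensus(cons, resistance, seed = NULL)
}

#' Recluster oversized modules
#'
#' Iteratively splits every module larger than `max_size` by running
#' Louvain on its induced subgraph and replacing the module with the
#' sub-partition. A module that the sub-clusterer refuses to split
#' (returns a single community) is kept and marked unsplittable. Labels
#' are recompacted; the procedure only ever refines the input partition.
#'
#' @param g a weighted graph.
#' @param p a partition of `g`.
#' @param max_size size above which a module is split (default 100, the
#'   upper end of the disease-module size range).
#' @param resistance resistance for the subgraph Louvain runs.
#' @param seed optional RNG seed.
#' @return a named integer partition refining `p`.
#' @export
recluster_large <- function(g, p, max_size = 100, resistance = 0.1, seed = NULL) {
  .check_graph(g)
  p <- .validate_partition(g, p)
  if (!is.null(seed)) set.seed(seed)
  modules <- unname(partition_to_modules(p))
  unsplittable <- rep(FALSE, length(modules))
  repeat {
    big <- which(lengths(modules) > max_size & !unsplittable)
    if (length(big) == 0) break
    i <- big[1]
    sub <- igraph::induced_subgraph(g, modules[[i]])
    subp <- louvain_partition(sub, resistance = resistance)
    if (max(subp) == 1L) {
      unsplittable[i] <- TRUE
      next
    }
    pieces <- unname(partition_to_modules(subp))
    modules <- c(modules[-i], pieces)
    unsplittable <- c(unsplittable[-i], rep(FALSE, length(pieces)))
  }
  modules_to_partition(modules)
}

#' Minimum-outgoing-edges core of a module
#'
#' For modules larger than `size_trigger`, ranks the members by core
#' score ([core_scores()], ascending: fewest outgoing relative to internal
#' edges first) and keeps the best `core_size` nodes as the core; smaller
#' modules are returned unchanged. Ties are broken by higher internal
#' weight, then lexicographic node id. The default core size of 60
#' reflects the empirical average size of a disease module.
#'
#' @param g a weighted graph.
#' @param m a module (character vector of member node names).
#' @param core_size number of nodes kept (default 60).
#' @param size_trigger only modules strictly larger than this are reduced
#'   (default 100).
#' @return a character vector, the core node set (`m` itself if small).
#' @export
min_outgoing_core <- function(g, m, core_size = 60, size_trigger = 100) {
  m <- .check_members(g, m)
  if (length(m) <= size_trigger) return(m)
  sc <- core_scores(g, m)
  sub <- igraph::induced_subgraph(g, m)
  w_in <- igraph::strength(sub)[m]
  ord <- order(sc, -w_in, m)
  m[ord][seq_len(min(core_size, length(m)))]
}

#' Apply [min_outgoing_core()] to every module of a partition
#'
#' @param g a weighted graph.
#' @param p a partition.
#' @inheritParams min_outgoing_core
#' @return a named list of module node sets (cores).
#' @export
min_outgoing_cores <- function(g, p, core_size = 60, size_trigger = 100) {
  lapply(partition_to_modules(p), function(m)
    min_outgoing_core(g, m, core_size = core_size, size_trigger = size_trigger))
}
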