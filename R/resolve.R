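# Resolution of overlapping covers into non-overlapping partitions.

#' Base communities and overlap set of a cover
#'
#' Nodes with exactly one module label form the *base* partition; nodes
#' with two or more labels form the *overlap* set; nodes with no label are
#' excluded. Resolution methods assign each overlap node to one of its own
#' candidate base communities.
#'
#' @param cover a named list of modules (character vectors), overlaps
#'   permitted.
#' @return a list with `base` (named character vector node -> module
#'   label), `overlap` (character vector) and `candidates` (named list,
#'   overlap node -> its module labels).
#' @export
base_communities <- function(cover) {
  if (length(cover) == 0) stop("empty cover", call. = FALSE)
  if (is.null(names(cover))) names(cover) <- as.character(seq_along(cover))
  if (any(lengths(cover) == 0)) stop("cover contains an empty module", call. = FALSE)
  node <- unlist(cover, use.names = FALSE)
  lab <- rep(names(cover), lengths(cover))
  k <- table(node)
  singles <- names(k)[k == 1]
  if (length(singles) == 0) {
    stop("every node is in the overlap; no base communities to assign into",
         call. = FALSE)
  }
  base <- stats::setNames(lab[match(singles, node)], singles)
  over <- sort(names(k)[k >= 2])
  cands <- lapply(over, function(v) sort(unique(lab[node == v])))
  names(cands) <- over
  list(base = base, overlap = over, candidates = cands)
}

# Conductance of a node set given precomputed degree vector and graph;
# returns Inf for degenerate sets so they are never preferred.
.safe_conductance <- function(g, members) {
  tryCatch(conductance(g, members), error = function(e) Inf)
}

#' Resolve a cover into a partition
#'
#' Three strategies for assigning each overlap node to one of its
#' candidate base communities:
#'
#' * `assign_random()`: uniformly at random among the node's own
#'   candidate modules (seeded); with `global = TRUE`, among all base
#'   communities.
#' * `assign_conductance()`: each overlap node independently joins the
#'   candidate base community whose conductance after including the node
#'   is minimal. Independence means late assignments can degrade the
#'   structure formed by earlier ones.
#' * `assign_iterative()`: sequential assignment (lexicographic node
#'   order) with community recomputation after every placement, followed
#'   by reassignment phases — each overlap node is extracted and re-placed
#'   by minimum conductance — until a phase moves no node or `max_phases`
#'   is reached. Empirically converges in a few (typically 3-5) phases.
#'
#' @param g a weighted graph.
#' @param cover a named list of modules.
#' @param seed RNG seed (random assignment).
#' @param global assign among all base communities instead of the node's
#'   candidates (random assignment only).
#' @param max_phases cap on reassignment phases (iterative assignment).
#' @return a named character vector node -> module label over the cover's
#'   nodes; for `assign_iterative()` with attributes `phases` (number of
#'   reassignment phases run) and `converged`.
#' @export
assign_random <- function(g, cover, seed = NULL, global = FALSE) {
  bc <- base_communities(cover)
  if (!is.null(seed)) set.seed(seed)
  out <- bc$base
  pool <- unique(bc$base)
  for (v in bc$overlap) {
    cand <- if (global) pool else intersect(bc$candidates[[v]], pool)
    if (length(cand) == 0) cand <- pool
    out[[v]] <- if (length(cand) == 1) cand else sample(cand, 1)
  }
  out
}

#' @rdname assign_random
#' @export
assign_conductance <- function(g, cover) {
  .check_graph(g)
  bc <- base_communities(cover)
  sets <- split(names(bc$base), bc$base)
  out <- bc$base
  for (v in bc$overlap) {
    cand <- intersect(bc$candidates[[v]], names(sets))
    if (length(cand) == 0) cand <- names(sets)
    cond <- vapply(cand, function(l) .safe_conductance(g, c(sets[[l]], v)), 0)
    out[[v]] <- cand[order(cond, cand)][1]
  }
  out
}

#' @rdname assign_random
#' @export
assign_iterative <- function(g, cover, max_phases = 50) {
  .check_graph(g)
  bc <- base_communities(cover)
  sets <- split(names(bc$base), bc$base)
  labels <- names(sets)
  place <- function(v, current_sets, exclude_from = NULL) {
    cand <- intersect(bc$candidates[[v]], labels)
    if (length(cand) == 0) cand <- labels
    cond <- vapply(cand, function(l) {
      s <- current_sets[[l]]
      if (!is.null(exclude_from) && exclude_from == l) s <- setdiff(s, v)
      .safe_conductance(g, union(s, v))
    }, 0)
    cand[order(cond, cand)][1]
  }
  assign_to <- stats::setNames(character(length(bc$overlap)), bc$overlap)
  for (v in bc$overlap) {                 # initial sequential phase
    l <- place(v, sets)
    assign_to[[v]] <- l
    sets[[l]] <- c(sets[[l]], v)
  }
  phases <- 0L
  converged <- FALSE
  while (phases < max_phases) {
    phases <- phases + 1L
    moved <- 0L
    for (v in bc$overlap) {               # reassignment phase
      cur <- assign_to[[v]]
      sets[[cur]] <- setdiff(sets[[cur]], v)
      l <- place(v, sets)
      assign_to[[v]] <- l
      sets[[l]] <- c(sets[[l]], v)
      if (l != cur) moved <- moved + 1L
    }
    if (moved == 0L) { converged <- TRUE; break }
  }
  if (!converged) warning("iterative assignment did not converge in ",
                          max_phases, " phases", call. = FALSE)
  out <- c(bc$base, assign_to)
  structure(out[sort(names(out))], phases = phases, converged = converged)
}

#' Per-node module membership counts of a cover
#'
#' @param cover a named list of modules.
#' @param nodes optional node names to report (non-members count 0);
#'   defaults to the cover's members.
#' @return a named integer vector of membership counts.
#' @export
overlap_counts <- function(cover, nodes = NULL) {
  members <- unlist(cover, use.names = FALSE)
  k <- table(members)
  if (is.null(nodes)) nodes <- sort(names(k))
  out <- stats::setNames(integer(length(nodes)), nodes)
  hit <- intersect(nodes, names(k))
  out[hit] <- as.integer(k[hit])
  out
}
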