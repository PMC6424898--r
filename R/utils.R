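# Internal helpers shared across modules.

# All user-facing functions operate on undirected, vertex-named igraph
# objects with a positive `weight` edge attribute. This check is the single
# entry gate; functions that build graphs internally are trusted.
.check_graph <- function(g) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("`g` must be undirected", call. = FALSE)
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name)) {
    stop("`g` must have named vertices", call. = FALSE)
  }
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    if (is.null(w)) stop("`g` must have a `weight` edge attribute", call. = FALSE)
    if (any(!is.finite(w)) || any(w <= 0)) {
      stop("edge weights must be finite and strictly positive", call. = FALSE)
    }
    if (igraph::any_loop(g)) stop("`g` must not contain self-loops", call. = FALSE)
  }
  invisible(g)
}

# Total edge weight e, so that sum(strength) == 2e.
.total_weight <- function(g) {
  if (igraph::ecount(g) == 0) return(0)
  sum(igraph::E(g)$weight)
}

.check_members <- function(g, members) {
  members <- as.character(members)
  if (length(members) == 0) stop("module must be non-empty", call. = FALSE)
  if (anyDuplicated(members)) members <- unique(members)
  missing <- setdiff(members, igraph::V(g)$name)
  if (length(missing) > 0) {
    stop("module members not in graph: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  members
}

# Internal edge weight, cut weight and volume of a node set.
# Invariant: vol == 2 * internal + cut.
.module_stats <- function(g, members) {
  d <- igraph::strength(g)
  vol <- sum(d[members])
  sub <- igraph::induced_subgraph(g, members)
  w_int <- if (igraph::ecount(sub) > 0) sum(igraph::E(sub)$weight) else 0
  list(internal = w_int, cut = vol - 2 * w_int, volume = vol)
}

#' Coerce a community labelling to a canonical partition
#'
#' A partition is represented as a named integer vector mapping every node
#' to a community label; labels are recoded to be contiguous `1..k` in
#' order of first appearance.
#'
#' @param x a named vector of community labels (integer, character or factor).
#' @return a named integer vector with contiguous labels `1..k`.
#' @export
as_partition <- function(x) {
  if (is.null(names(x))) stop("partition must be a named vector", call. = FALSE)
  labels <- as.character(x)
  out <- match(labels, unique(labels))
  names(out) <- names(x)
  out
}

#' Split a partition into a list of modules
#'
#' @param p a named partition vector (see [as_partition()]).
#' @return a list of character vectors, one per community, named by label.
#' @export
partition_to_modules <- function(p) {
  split(names(p), p)
}

#' Turn a list of disjoint modules into a partition
#'
#' @param modules a list of character vectors with disjoint members.
#' @return a named integer partition.
#' @export
modules_to_partition <- function(modules) {
  nodes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(nodes)) stop("modules overlap; not a partition", call. = FALSE)
  p <- rep(seq_along(modules), lengths(modules))
  names(p) <- nodes
  as_partition(p)
}

.validate_partition <- function(g, p) {
  if (!setequal(names(p), igraph::V(g)$name)) {
    stop("partition must cover exactly the graph's nodes", call. = FALSE)
  }
  p[igraph::V(g)$name]
}
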