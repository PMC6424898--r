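# GWAS enrichment evaluation, clusterability scoring, reporting
# arithmetic and trait comorbidity networks.

#' Clusterability of a gene set's largest connected component
#'
#' Extracts the largest connected component of the subgraph induced by
#' `genes` ([largest_connected_component()]) and scores that node set as a
#' single community: modularity and conductance. Known disease-gene sets
#' typically score poorly on both, which is why purely structural
#' clustering recovers few disease modules.
#'
#' @param g a weighted graph.
#' @param genes a character vector of gene/node names.
#' @return a list with `modularity`, `conductance`, and the `lcc` node
#'   set.
#' @export
lcc_clusterability <- function(g, genes) {
  lcc <- largest_connected_component(g, genes)
  if (length(lcc) < 2) {
    stop("LCC has a single node; conductance undefined", call. = FALSE)
  }
  list(modularity = modularity_score(g, lcc),
       conductance = conductance(g, lcc),
       lcc = lcc)
}

#' Fisher-method enrichment of modules against gene scores
#'
#' A simplified module scorer standing in for pathway-scoring pipelines
#' such as PASCAL (no SNP aggregation or LD correction is performed; the
#' interface also accepts externally computed calls, see
#' [as_enrichment()]): for every (module, trait) pair the member genes'
#' p-values are combined with Fisher's method (`-2 * sum(log p)` against
#' a chi-square with `2k` degrees of freedom; genes missing from the
#' score table, or with `NA` for a trait, are imputed `p = 1`). The raw
#' p-values are Benjamini-Hochberg adjusted across all (module, trait)
#' pairs, and a pair is *enriched* when its q-value is at most `fdr`. A
#' module is disease-enriched when it is enriched for at least one trait.
#'
#' @param modules a cover (named list of node sets) or a partition.
#' @param scores a numeric matrix of p-values, rows = genes, columns =
#'   traits.
#' @param fdr false-discovery-rate level (default 0.05).
#' @return a data.frame with columns `module`, `trait`, `n_genes`,
#'   `n_scored`, `p`, `q`, `enriched`, and attribute `fdr`.
#'   Modules with no scored gene are excluded with a warning.
#' @export
enrich_modules <- function(modules, scores, fdr = 0.05) {
  if (!is.list(modules)) modules <- partition_to_modules(modules)
  if (is.null(names(modules))) names(modules) <- as.character(seq_along(modules))
  if (fdr <= 0 || fdr >= 1) stop("`fdr` must be in (0, 1)", call. = FALSE)
  scores <- as.matrix(scores)
  traits <- colnames(scores)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(scores)))
  scored_any <- vapply(modules, function(m) any(m %in% rownames(scores)), TRUE)
  if (any(!scored_any)) {
    warning(sum(!scored_any), " module(s) with no scored gene excluded", call. = FALSE)
    modules <- modules[scored_any]
  }
  if (length(modules) == 0) stop("no module has scored genes", call. = FALSE)
  rows <- lapply(names(modules), function(lab) {
    m <- modules[[lab]]
    idx <- match(m, rownames(scores))
    k <- length(m)
    vapply(seq_along(traits), function(j) {
      p <- scores[idx[!is.na(idx)], j]
      p <- p[!is.na(p)]
      p <- pmin(pmax(p, 1e-300), 1)
      stat <- -2 * sum(log(p))          # imputed p = 1 contribute 0
      stats::pchisq(stat, df = 2 * k, lower.tail = FALSE)
    }, 0)
  })
  out <- data.frame(
    module = rep(names(modules), each = length(traits)),
    trait = rep(traits, times = length(modules)),
    n_genes = rep(lengths(modules), each = length(traits)),
    n_scored = rep(vapply(modules, function(m) sum(m %in% rownames(scores)), 0L),
                   each = length(traits)),
    p = unlist(rows),
    row.names = NULL, stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q <= fdr
  attr(out, "fdr") <- fdr
  out
}

#' Import externally computed enrichment calls
#'
#' Wraps per-(module, trait) enrichment calls produced outside the
#' package (e.g. by a full pathway-scoring tool) into the same shape
#' [enrich_modules()] returns, so downstream reporting and comorbidity
#' construction can consume them.
#'
#' @param calls a data.frame with columns `module`, `trait` and
#'   `enriched` (logical); optional `p` and `q`.
#' @param fdr the FDR level the calls were made at.
#' @return a data.frame in the [enrich_modules()] shape.
#' @export
as_enrichment <- function(calls, fdr = 0.05) {
  need <- c("module", "trait", "enriched")
  if (!all(need %in% names(calls))) {
    stop("`calls` needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(calls)
  if (is.null(out$p)) out$p <- NA_real_
  if (is.null(out$q)) out$q <- NA_real_
  attr(out, "fdr") <- fdr
  out
}

#' Per-module any-trait enrichment flags
#'
#' @param enr an enrichment result ([enrich_modules()]).
#' @return a named logical vector over modules.
#' @export
enriched_any <- function(enr) {
  flags <- tapply(enr$enriched, enr$module, any)
  stats::setNames(as.logical(flags), names(flags))
}

#' Hit ratio: fraction of predicted modules that are enriched
#'
#' @param n_enriched number of enriched modules.
#' @param n_predicted number of predicted modules (`> 0`).
#' @return `n_enriched / n_predicted`.
#' @export
hit_ratio <- function(n_enriched, n_predicted) {
  if (n_predicted <= 0) stop("`n_predicted` must be > 0", call. = FALSE)
  if (n_enriched < 0 || n_enriched > n_predicted) {
    stop("need 0 <= n_enriched <= n_predicted", call. = FALSE)
  }
  n_enriched / n_predicted
}

#' Method score: total enriched modules across networks
#'
#' @param per_network_enriched non-negative counts of enriched modules,
#'   one per network.
#' @return their sum (0 for an empty list).
#' @export
method_score <- function(per_network_enriched) {
  counts <- as.numeric(per_network_enriched)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  sum(counts)
}

#' Trait comorbidity network from enrichment results
#'
#' For every module enriched for two or more traits, every pair of those
#' traits is linked and the pair's count incremented (the count is the
#' number of modules jointly enriched for both traits). The top
#' `ceiling(top_frac * n_edges)` edges by count are retained; edges tied
#' with the cutoff count are all kept.
#'
#' @param enr an enrichment result ([enrich_modules()]).
#' @param top_frac fraction of edges kept (default 0.5).
#' @return an undirected igraph over traits with an integer `count` edge
#'   attribute (empty, with a warning, if no module is enriched for
#'   multiple traits).
#' @export
comorbidity_network <- function(enr, top_frac = 0.5) {
  if (top_frac <= 0 || top_frac > 1) stop("`top_frac` must be in (0, 1]", call. = FALSE)
  hits <- enr[enr$enriched, , drop = FALSE]
  by_mod <- split(hits$trait, hits$module)
  by_mod <- by_mod[lengths(by_mod) >= 2]
  if (length(by_mod) == 0) {
    warning("no module enriched for >= 2 traits; empty comorbidity network",
            call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  pairs <- do.call(rbind, lapply(by_mod, function(tr) {
    tr <- sort(unique(tr))
    t(utils::combn(tr, 2))
  }))
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  cnt <- table(key)
  counts <- as.integer(cnt)
  ab <- strsplit(names(cnt), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(ab, `[[`, "", 1),
                      to = vapply(ab, `[[`, "", 2),
                      count = counts, stringsAsFactors = FALSE)
  keep_n <- ceiling(top_frac * nrow(edges))
  cutoff <- sort(edges$count, decreasing = TRUE)[keep_n]
  edges <- edges[edges$count >= cutoff, , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE)
}
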