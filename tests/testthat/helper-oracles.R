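# Independent brute-force oracles and small graph builders.
# The oracles evaluate the quality formulas by direct double loops over
# the dense adjacency matrix and are kept free of any package internals.

library(igraph)

g_from_edges <- function(from, to, weight = 1) {
  graph_from_data_frame(
    data.frame(from = from, to = to,
               weight = rep_len(weight, length(from))),
    directed = FALSE)
}

# two disjoint triangles a-b-c, d-e-f
g_two_triangles <- function() {
  g_from_edges(c("a", "b", "a", "d", "e", "d"), c("b", "c", "c", "e", "f", "f"))
}

g_clique <- function(nodes, weight = 1) {
  pr <- t(combn(nodes, 2))
  g_from_edges(pr[, 1], pr[, 2], weight)
}

# disjoint union preserving the weight attribute
g_union <- function(...) {
  gs <- list(...)
  ed <- do.call(rbind, lapply(gs, as_data_frame, what = "edges"))
  vt <- unlist(lapply(gs, function(g) V(g)$name))
  graph_from_data_frame(ed[, c("from", "to", "weight")], directed = FALSE,
                        vertices = data.frame(name = vt))
}

# random weighted graph over n named nodes, edge prob p
g_random <- function(n, p = 0.5, weighted = TRUE) {
  nodes <- sprintf("v%02d", seq_len(n))
  pr <- t(combn(nodes, 2))
  keep <- runif(nrow(pr)) < p
  pr <- pr[keep, , drop = FALSE]
  w <- if (weighted) round(runif(nrow(pr), 0.1, 2), 3) else rep(1, nrow(pr))
  g <- graph_from_data_frame(
    data.frame(from = pr[, 1], to = pr[, 2], weight = w),
    directed = FALSE, vertices = data.frame(name = nodes))
  g
}

adj_of <- function(g) {
  A <- as.matrix(as_adjacency_matrix(g, attr = if (ecount(g)) "weight" else NULL))
  A[V(g)$name, V(g)$name, drop = FALSE]
}

# Eq. 1 by double loop over ordered pairs, i != j
oracle_modularity <- function(g, modules, gamma = 1) {
  if (!is.list(modules)) modules <- list(modules)
  A <- adj_of(g)
  d <- rowSums(A)
  e2 <- sum(A)                       # 2e
  total <- 0
  for (m in modules) {
    for (i in m) for (j in m) {
      if (i == j) next
      total <- total + A[i, j] - gamma * d[i] * d[j] / e2
    }
  }
  unname(total / e2)
}

oracle_conductance <- function(g, m) {
  A <- adj_of(g)
  d <- rowSums(A)
  inm <- rownames(A) %in% m
  cut <- sum(A[inm, !inm, drop = FALSE])
  denom <- min(sum(d[inm]), sum(d[!inm]))
  if (cut == 0) 0 else cut / denom
}

oracle_ceil <- function(g, m) {
  A <- adj_of(g)
  inm <- rownames(A) %in% m
  n_c <- sum(inm)
  if (n_c < 2) return(0)
  w_int <- sum(A[inm, inm]) / 2
  if (w_int == 0) return(0)
  cut <- sum(A[inm, !inm, drop = FALSE])
  (w_int / choose(n_c, 2)) * (w_int / (w_int + cut))
}

oracle_core_score <- function(g, m, node) {
  A <- adj_of(g)
  inm <- rownames(A) %in% m
  w_in <- sum(A[node, inm]) - A[node, node]
  w_out <- sum(A[node, !inm])
  if (w_out == 0) 0 else if (w_in == 0) Inf else w_out / w_in
}

# all set partitions of a vector (Bell-number many; keep inputs small)
all_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- all_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(x[1]), p)
  }
  out
}

# direct BH step-up on a p-value vector
oracle_bh_reject <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= alpha * seq_len(n) / n)))
  rejected <- logical(n)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  rejected
}

f1_sets <- function(a, b) {
  i <- length(intersect(a, b))
  if (i == 0) return(0)
  pr <- i / length(a); rc <- i / length(b)
  2 * pr * rc / (pr + rc)
}

ari <- function(a, b) {
  nodes <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(as.integer(a[nodes]), as.integer(b[nodes]))
}

expect_valid_partition <- function(p, g) {
  expect_setequal(names(p), igraph::V(g)$name)
  expect_true(all(sort(unique(as.integer(p))) == seq_len(max(p))))
}
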