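test_that("Louvain recovers the modularity-optimal split of bridged cliques", {
  # two K4s joined by one edge: exhaustive search over all set partitions
  # confirms the two cliques maximize modularity, and Louvain finds them
  nodes_a <- paste0("a", 1:4); nodes_b <- paste0("b", 1:4)
  g <- g_union(g_clique(nodes_a), g_clique(nodes_b))
  g <- add_edges(g, c("a1", "b1"), weight = 1)
  parts <- all_partitions(V(g)$name)
  best <- parts[[which.max(vapply(parts, function(p) oracle_modularity(g, p), 0))]]
  expect_setequal(lapply(best, sort), list(sort(nodes_a), sort(nodes_b)))
  p <- louvain_partition(g, resistance = 1, seed = 4)
  expect_valid_partition(p, g)
  expect_setequal(unname(lapply(partition_to_modules(p), sort)),
                  list(sort(nodes_a), sort(nodes_b)))
})

test_that("Louvain is deterministic given a seed and respects components", {
  set.seed(20)
  g <- g_random(30, 0.15)
  expect_identical(louvain_partition(g, seed = 99), louvain_partition(g, seed = 99))
  # no community spans two components
  g2 <- g_two_triangles()
  p <- louvain_partition(g2, resistance = 1, seed = 1)
  comp <- components(g2)$membership
  for (m in partition_to_modules(p)) {
    expect_equal(length(unique(comp[m])), 1)
  }
  expect_error(louvain_partition(make_empty_graph(0, directed = FALSE)), "empty")
})

test_that("MCL agrees with a direct dense simulation of the matrix iteration", {
  g <- g_two_triangles()
  # oracle: dense base-R simulation of expansion/inflation with self-loops
  A <- adj_of(g) + diag(6)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in 1:100) {
    Mn <- M %*% M
    Mn <- Mn^2
    Mn <- sweep(Mn, 2, colSums(Mn), "/")
    # column stochasticity is preserved by every inflation step
    expect_equal(colSums(Mn), rep(1, 6), tolerance = 1e-9, ignore_attr = TRUE)
    if (max(abs(Mn - M)) < 1e-8) { M <- Mn; break }
    M <- Mn
  }
  pat <- (M + t(M)) > 0
  oracle <- components(graph_from_adjacency_matrix(pat, mode = "undirected"))
  p <- mcl_partition(g, inflation = 2)
  expect_valid_partition(p, g)
  expect_equal(ari(p, setNames(oracle$membership, V(g)$name)), 1)
  expect_setequal(unname(lapply(partition_to_modules(p), sort)),
                  list(c("a", "b", "c"), c("d", "e", "f")))
})

test_that("MCL clusters a single edge together and coarsens with low inflation", {
  g <- g_from_edges("a", "b", 0.7)
  expect_equal(max(mcl_partition(g)), 1)
  # ring of 4 triangles: cluster count is non-decreasing in inflation
  blocks <- lapply(1:4, function(b) paste0("c", b, letters[1:3]))
  g2 <- do.call(g_union, lapply(blocks, g_clique))
  g2 <- add_edges(g2, c("c1a", "c2a", "c2b", "c3a", "c3b", "c4a", "c4b", "c1b"),
                  weight = 0.5)
  ks <- vapply(2:6, function(I) max(mcl_partition(g2, inflation = I)), 0L)
  expect_true(all(diff(ks) >= 0))
})

test_that("CEIL clustering finds the exhaustive optimum on bridged cliques", {
  nodes_a <- paste0("a", 1:4); nodes_b <- paste0("b", 1:4)
  g <- g_union(g_clique(nodes_a), g_clique(nodes_b))
  parts <- all_partitions(V(g)$name)
  objs <- vapply(parts, function(pt) ceil_objective(g, modules_to_partition(pt)), 0)
  best <- parts[[which.max(objs)]]
  expect_setequal(lapply(best, sort), list(sort(nodes_a), sort(nodes_b)))
  p <- ceil_partition(g)
  expect_valid_partition(p, g)
  expect_setequal(unname(lapply(partition_to_modules(p), sort)),
                  list(sort(nodes_a), sort(nodes_b)))
  expect_equal(ceil_objective(g, p), max(objs))
  # a single clique stays one community (CEIL = 1 is maximal)
  k5 <- g_clique(paste0("x", 1:5))
  expect_equal(max(ceil_partition(k5)), 1)
  # greedy contract: result at least as good as the singleton start
  set.seed(5)
  g3 <- g_random(15, 0.3)
  singles <- setNames(seq_len(15), V(g3)$name)
  expect_gte(ceil_objective(g3, ceil_partition(g3)), ceil_objective(g3, singles))
})
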