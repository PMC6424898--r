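test_that("consensus similarity implements qualified Jaccard on label vectors", {
  nodes <- c("a", "b", "c", "d")
  p1 <- setNames(c(1, 1, 2, 2), nodes)
  p2 <- setNames(c(1, 2, 1, 2), nodes)   # a,b apart; a,c together
  # identical base partitions: co-members reach similarity 1
  cons <- consensus_network(list(p1, p1, p1))
  ed <- igraph::as_data_frame(cons)
  expect_equal(nrow(ed), 2)
  expect_equal(ed$weight, c(1, 1))
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_setequal(key, c("a b", "c d"))
  # together in 1 of 2 clusterings: a/(2r-a) = 1/3, below 0.5, no edge
  cons2 <- consensus_network(list(p1, p2))
  expect_equal(ecount(cons2), 0)
  cons3 <- consensus_network(list(p1, p2), threshold = 0.3)
  expect_true(all(abs(E(cons3)$weight - 1 / 3) < 1e-12))
  # simple matching form: 1/2, still not > 0.5
  expect_equal(ecount(consensus_network(list(p1, p2), method = "simple")), 0)
  expect_error(consensus_network(list()), "at least one")
})

test_that("ensemble of agreeing base runs reproduces their partition", {
  g <- g_two_triangles()
  runs <- list(list(method = "louvain", resistance = 1),
               list(method = "mcl", inflation = 2),
               list(method = "ceil"))
  p <- ensemble_cluster(g, runs, seed = 1)
  expect_valid_partition(p, g)
  truth <- setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "d", "e", "f"))
  expect_equal(ari(p, truth), 1)
  expect_error(ensemble_cluster(g, list()), "non-empty")
})

test_that("ensemble with the full baseline grid recovers planted blocks", {
  b <- planted_partition(rep(20, 4), seed = 207)
  p <- ensemble_cluster(b$graph, baseline_runs(), seed = 207)
  expect_valid_partition(p, b$graph)
  expect_gte(ari(p, b$truth), 0.9)
})

test_that("perturbation consensus reduces to plain Louvain when nothing is dropped", {
  b <- planted_partition(rep(15, 3), seed = 31)
  p0 <- perturbation_cluster(b$graph, drop_frac = 0, iterations = 5, seed = 1)
  base <- louvain_partition(b$graph, resistance = 0.1, seed = 1)
  expect_equal(ari(p0, base), 1)
  # a single iteration is just the clustering of that one perturbed copy
  p1 <- perturbation_cluster(b$graph, drop_frac = 0.05, iterations = 1, seed = 2)
  expect_valid_partition(p1, b$graph)
  # dropping every edge is an unrecoverable perturbation
  g1 <- g_from_edges("a", "b", 1)
  expect_error(perturbation_cluster(g1, drop_frac = 1, iterations = 2),
               "drop_frac")
})

test_that("reclustering splits oversized modules and only ever refines", {
  # two K10s bridged by one edge, forced into a single 20-node module
  na <- paste0("a", 1:10); nb <- paste0("b", 1:10)
  g <- g_union(g_clique(na), g_clique(nb))
  g <- add_edges(g, c("a1", "b1"), weight = 1)
  p_one <- setNames(rep(1, 20), V(g)$name)
  p <- recluster_large(g, p_one, max_size = 15)
  expect_setequal(unname(lapply(partition_to_modules(p), sort)),
                  list(sort(na), sort(nb)))
  # already-small partitions come back unchanged
  p_small <- modules_to_partition(list(na, nb))
  expect_equal(recluster_large(g, p_small, max_size = 15), p_small)
  # refinement-only: output modules never mix input modules
  set.seed(8)
  g2 <- planted_partition(rep(12, 4), seed = 8)$graph
  p_in <- louvain_partition(g2, resistance = 0.1, seed = 8)
  p_out <- recluster_large(g2, p_in, max_size = 8)
  for (m in partition_to_modules(p_out)) {
    expect_equal(length(unique(p_in[m])), 1)
  }
})

test_that("minimum-outgoing cores keep the best-ranked members", {
  b <- planted_partition(c(120, 15), p_in = 0.25, p_out = 0.02, seed = 12)
  g <- b$graph
  big <- b$modules[["1"]]
  expect_identical(min_outgoing_core(g, big[1:100]), big[1:100])  # at trigger
  core <- min_outgoing_core(g, big)                               # |m| = 120
  expect_length(core, 60)
  expect_true(all(core %in% big))
  sc <- core_scores(g, big)
  expect_lte(max(sc[core]), min(sc[setdiff(big, core)]))  # ranking contract
  expect_lte(mean(sc[core][is.finite(sc[core])]),
             mean(sc[is.finite(sc)]))
})
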