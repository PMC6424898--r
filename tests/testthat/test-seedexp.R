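test_that("disease seeds are the union of sub-threshold genes present in the graph", {
  g <- g_two_triangles()
  sc <- matrix(c(1e-5, 1e-3, 0.5,
                 0.2,  1e-5, 0.9), ncol = 2,
               dimnames = list(c("a", "b", "zz"), c("t1", "t2")))
  s <- disease_seeds(sc, g, 1e-4)
  expect_equal(as.character(s), c("a", "b"))   # b passes in t2 only; zz absent
  expect_equal(as.character(disease_seeds(sc, g, 1e-6)), character(0)) |>
    expect_warning("no gene")
})

test_that("HITS seeds follow the principal eigenvector of the adjacency", {
  star <- g_from_edges(rep("hub", 5), paste0("leaf", 1:5))
  expect_equal(as.character(hits_seeds(star, 1)), "hub")
  # clique: all scores tie, lexicographic rule
  k4 <- g_clique(c("d", "b", "c", "a"))
  expect_equal(as.character(hits_seeds(k4, 2)), c("a", "b"))
  expect_length(hits_seeds(k4, 4), 4)
  expect_error(hits_seeds(k4, 5), "k")
  # cross-check against an independent eigenvector computation
  set.seed(14)
  g <- g_random(20, 0.3)
  ev <- igraph::eigen_centrality(g)$vector
  expect_equal(as.character(hits_seeds(g, 5)),
               names(sort(-ev))[1:5])
})

test_that("spread hubs mark neighborhoods and never overlap them", {
  star <- g_from_edges(rep("hub", 5), paste0("leaf", 1:5))
  expect_equal(as.character(spread_hub_seeds(star, 1)), "hub")
  # two disjoint stars: both centers selected
  g2 <- g_from_edges(c(rep("h1", 4), rep("h2", 3)),
                     c(paste0("u", 1:4), paste0("v", 1:3)))
  expect_setequal(as.character(spread_hub_seeds(g2, 2)), c("h1", "h2"))
  expect_warning(s <- spread_hub_seeds(g2, 5), "attainable")
  expect_length(s, 2)
})

test_that("PPR pushes conserve mass and meet the residual bound", {
  set.seed(15)
  g <- g_random(25, 0.2)
  g <- g + vertices("island")
  d <- strength(g)
  for (seed_node in c("v01", "v13", "island")) {
    pv <- ppr(g, seed_node, alpha = 0.85, eps = 1e-5)
    expect_equal(sum(pv$score) + sum(pv$residual), 1, tolerance = 1e-9)
    expect_true(all(pv$score >= 0))
    pos <- d > 0
    expect_true(all(pv$residual[pos] < 1e-5 * d[pos]))
  }
  # isolated seed keeps all its mass
  pv <- ppr(g, "island")
  expect_equal(pv$score[["island"]], 1)
  expect_equal(sum(pv$score) - pv$score[["island"]], 0)
  # clique symmetry: all non-seed scores equal
  k5 <- g_clique(paste0("x", 1:5))
  pv5 <- ppr(k5, "x1", eps = 1e-8)
  others <- pv5$score[paste0("x", 2:5)]
  expect_lt(diff(range(others)), 1e-6)
})

test_that("PPR agrees with an independent personalized PageRank solver", {
  set.seed(16)
  g <- g_random(30, 0.25)
  reset <- as.numeric(V(g)$name == "v07")
  exact <- igraph::page_rank(g, personalized = reset, damping = 0.15)$vector
  pv <- ppr(g, "v07", alpha = 0.85, eps = 1e-9)
  expect_equal(unname(pv$score[V(g)$name]), unname(exact), tolerance = 1e-4)
})

test_that("seed expansion returns the modularity-maximal prefix", {
  # a seed inside a disjoint K6 expands to exactly the clique
  k6 <- g_clique(paste0("k", 1:6))
  set.seed(17)
  rest <- g_random(20, 0.25)
  g <- g_union(k6, rest)
  m <- expand_seed(g, "k3")
  expect_setequal(m, paste0("k", 1:6))
  expect_identical(expand_seed(g, "k3"), expand_seed(g, "k3"))  # deterministic
  expect_true(length(m) >= 3 && length(m) <= 100)
  # an isolated seed cannot reach the minimum size
  g2 <- g + vertices("alone")
  expect_warning(out <- expand_seed(g2, "alone"), "rejected")
  expect_null(out)
})

test_that("expanding all seeds deduplicates and spans components", {
  k6 <- g_clique(paste0("k", 1:6))
  k5 <- g_clique(paste0("m", 1:5))
  g <- g_union(k6, k5)
  res <- suppressWarnings(expand_all(g, c("k1", "k2", "m1")))
  expect_length(res$cover, 2)                       # k1/k2 deduplicated
  expect_equal(res$seed_map[["k1"]], res$seed_map[["k2"]])
  mods <- res$cover
  expect_length(intersect(mods[[1]], mods[[2]]), 0) # disjoint components
})

test_that("expansion from causal seeds recovers planted modules", {
  b <- planted_partition(rep(25, 4), seed = 77)
  gs <- synth_gwas(b, n_traits = 3, seed = 78)
  seeds <- disease_seeds(gs, b$graph, 1e-4)
  res <- expand_all(b$graph, seeds)
  causal <- unique(unlist(attr(gs, "causal")))
  best <- vapply(causal, function(cm)
    max(vapply(res$cover, f1_sets, 0, b = b$modules[[cm]])), 0)
  expect_true(all(best >= 0.8))
  expect_true(all(lengths(res$cover) >= 3 & lengths(res$cover) <= 100))
  # every accepted module contains its seed
  for (s in names(res$seed_map)) {
    expect_true(s %in% res$cover[[res$seed_map[[s]]]])
  }
})
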