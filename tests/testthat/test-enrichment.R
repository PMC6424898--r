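test_that("Fisher-method enrichment flags exactly the BH step-up set", {
  set.seed(21)
  genes <- sprintf("x%03d", 1:90)
  scores <- matrix(runif(90 * 3), 90, 3,
                   dimnames = list(genes, paste0("t", 1:3)))
  mods <- split(genes, rep(1:30, each = 3))
  # spike a few (module, trait) cells so some rejections exist
  scores[mods[["3"]], 1] <- 1e-9
  scores[mods[["17"]], 2] <- 1e-7
  enr <- enrich_modules(mods, scores, fdr = 0.1)
  expect_equal(enr$enriched, oracle_bh_reject(enr$p, 0.1))
  expect_true(all(enr$q >= enr$p))
  expect_true(all(enr$enriched == (enr$q <= 0.1)))
})

test_that("enrichment handles flat, missing and unscored genes", {
  scores <- matrix(1, 4, 2, dimnames = list(letters[1:4], c("t1", "t2")))
  enr <- enrich_modules(list(M = letters[1:4]), scores)
  expect_false(any(enr$enriched))            # all p = 1: never enriched
  # genes absent from the table are imputed p = 1 (conservative df)
  scores2 <- matrix(1e-8, 2, 1, dimnames = list(c("a", "b"), "t1"))
  enr2 <- enrich_modules(list(M = c("a", "b", "zz", "ww")), scores2)
  enr3 <- enrich_modules(list(M = c("a", "b")), scores2)
  expect_gt(enr2$p, enr3$p)
  expect_warning(enrich_modules(list(M = c("a", "b"), bad = "qq"), scores2),
                 "no scored gene")
})

test_that("the uniform null is calibrated and planted signal is detected", {
  set.seed(22)
  genes <- sprintf("x%03d", 1:600)
  scores <- matrix(runif(600 * 5), 600, 5,
                   dimnames = list(genes, paste0("t", 1:5)))
  mods <- split(genes, rep(1:200, each = 3))
  enr <- enrich_modules(mods, scores, fdr = 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(enr))
  expect_lte(mean(enr$enriched), 0.05 + 2 * se)
  # one causal module for one trait: Beta(0.1, 1) p-values
  scores[mods[["42"]], 2] <- runif(3)^10
  enr2 <- enrich_modules(mods, scores, fdr = 0.05)
  expect_true(enr2$enriched[enr2$module == "42" & enr2$trait == "t2"])
})

test_that("hit ratios and method scores reproduce the printed tables", {
  expect_equal(round(hit_ratio(16, 872), 4), 0.0183)
  expect_equal(round(hit_ratio(9, 209), 4), 0.0431)
  expect_equal(hit_ratio(0, 10), 0)
  expect_error(hit_ratio(3, 0), "> 0")
  expect_error(hit_ratio(5, 3), "<=")
  expect_equal(method_score(c(16, 18, 9, 9, 4, 8)), 64)
  expect_equal(method_score(c(22, 21, 14, 20, 9, 10)), 96)
  expect_equal(method_score(c()), 0)
})

test_that("comorbidity networks accumulate joint enrichments and keep top edges", {
  calls <- data.frame(
    module = c("m1", "m1", "m2", "m2"),
    trait = c("X", "Y", "X", "Y"), enriched = TRUE)
  cn <- comorbidity_network(as_enrichment(calls), top_frac = 1)
  ed <- igraph::as_data_frame(cn)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$count, 2)                      # two modules share {X, Y}
  # tie rule: counts {3,2,2,1} at top_frac 0.5 keep {3,2,2}
  mk <- function(mod, traits) data.frame(module = mod, trait = traits, enriched = TRUE)
  calls2 <- rbind(mk("a1", c("P", "Q")), mk("a2", c("P", "Q")), mk("a3", c("P", "Q")),
                  mk("b1", c("P", "R")), mk("b2", c("P", "R")),
                  mk("c1", c("Q", "R")), mk("c2", c("Q", "R")),
                  mk("d1", c("Q", "S")))
  cn2 <- comorbidity_network(as_enrichment(calls2), top_frac = 0.5)
  ed2 <- igraph::as_data_frame(cn2)
  expect_setequal(ed2$count, c(3, 2, 2))
  # a single multi-trait module yields one edge of count 1
  cn3 <- comorbidity_network(as_enrichment(mk("z", c("X", "Y"))))
  expect_equal(igraph::as_data_frame(cn3)$count, 1)
  expect_warning(cm <- comorbidity_network(as_enrichment(mk("z", "X"))), "empty")
  expect_equal(vcount(cm), 0)
})

test_that("LCC clusterability scores mirror structural quality", {
  g <- g_two_triangles()
  lc <- lcc_clusterability(g, c("a", "b", "c"))
  expect_equal(lc$conductance, 0)               # whole component, zero cut
  expect_equal(lc$modularity, modularity_score(g, c("a", "b", "c")))
  expect_error(suppressWarnings(lcc_clusterability(g, "nope")), "no genes")
  # random sprinkles of a sparse graph cluster poorly
  set.seed(23)
  b <- planted_partition(rep(30, 4), p_in = 0.2, p_out = 0.05, seed = 23)
  nodes <- igraph::V(b$graph)$name
  conds <- replicate(10, {
    lcc_clusterability(b$graph, sample(nodes, 18))$conductance
  })
  expect_gt(mean(conds), 0.8)
})
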