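# coremod

Core disease module identification in weighted biological networks.

Protein interaction, signaling, co-expression and homology networks are
modular: densely interconnected gene groups share function, and disease
phenotypes arise when such a group malfunctions. Off-the-shelf community
detection adapts poorly to these networks — it returns a few giant
communities anchored on hub genes, while disease modules are small
(about 3–100 genes). `coremod` is for computational biologists who want
to extract small, structurally strong **core modules** from a weighted
network and test them for association with complex traits using GWAS
gene scores.

## What it implements

Given an undirected weighted graph with adjacency `A`, weighted degrees
`d_i = Σ_j A_ij` and total edge weight `e`:

* **Quality measures** — community modularity
  `Q(c) = (1/2e) Σ_{i≠j∈c} (A_ij − γ d_i d_j / 2e)` (self-pairs excluded
  from the null term), conductance `cut(c)/min(vol(c), vol(c̄))`, the
  CEIL score (internal density × separability), and a per-node core
  score `out(i)/in(i)` that ranks a module's structural core.
* **Baseline partitioners** — Louvain modularity maximization with a
  resistance (resolution) parameter, Markov clustering (expansion 2,
  inflation 2–9), and a CEIL-objective local-moving clusterer.
* **Four core-module frameworks** — consensus ensembles over a grid of
  base clusterings via pairwise Jaccard similarity of assignment
  vectors; perturbation consensus (drop 1% of edges, recluster, repeat);
  iterative reclustering of modules above 100 nodes; and
  minimum-outgoing-edge cores (top 60 nodes by core score of any module
  above 100).
* **Seed expansion** — disease seeds from gene p-values (cutoffs `1e-4`
  / `1e-6`), HITS hubs, or spread hubs; approximate personalized
  PageRank by residual pushes; expansion to the modularity-maximal
  prefix of the PPR ranking (sizes 3–100), yielding overlapping covers.
* **Overlap resolution** — random, minimum-conductance, and iterative
  minimum-conductance assignment of overlap nodes into base communities.
* **Evaluation** — Fisher's-method enrichment of modules against a
  gene-score table with Benjamini–Hochberg control at 5% FDR (a
  lightweight stand-in for pathway-scoring pipelines; external calls can
  be imported), hit ratios, method scores, LCC clusterability, and trait
  comorbidity networks (traits linked by the number of jointly enriched
  modules, top 50% of edges kept).
* **Synthetic benchmarks** — weighted planted-partition graphs
  (optionally with overlap nodes) and synthetic GWAS tables with
  `Beta(a, 1)` causal p-values, so the full pipeline runs and is tested
  without external data.

See `vignettes/core-modules.Rmd` for the methods account and design
rationale.

## Worked example

Build a benchmark with four planted 25-gene blocks, give three traits
causal signal in three of the blocks, and run the gold-standard-style
pipeline: disease seeds → PPR expansion → enrichment.

```r
library(coremod)

bench  <- planted_partition(sizes = rep(25, 4), p_in = 0.3, p_out = 0.01, seed = 42)
scores <- synth_gwas(bench, n_traits = 3, seed = 43)

seeds <- disease_seeds(scores, bench$graph, cutoff = 1e-4)
length(seeds)
#> [1] 28

res <- expand_all(bench$graph, seeds)
length(res$cover)
#> [1] 24

enr <- enrich_modules(res$cover, scores, fdr = 0.05)
table(enriched_any(enr))
#> TRUE
#>   24

head(score_modules(bench$graph, res$cover), 3)
#>   module size modularity conductance   ceil
#> 1     M1   25      0.180      0.0411 0.2171
#> 2     M2   35      0.156      0.2150 0.0888
#> 3     M3   24      0.172      0.0625 0.2165

hit_ratio(sum(enriched_any(enr)), length(res$cover))
#> [1] 1
```

The 28 seeds are the genes passing `1e-4` in at least one trait; all of
them sit in the three causal blocks (a causal gene passes with
probability `(1e-4)^0.1 ≈ 0.4`). Expansion returns 24 distinct modules,
every one enriched at 5% FDR, and the three causal blocks are each
recovered exactly (F1 = 1 against the planted truth); the fourth,
non-causal block attracts no seeds and no module. Module quality is
what the scores say: ~25-node modules with conductance near 0.04 are
tight, well-separated communities.

A command-line front end over the same functions is installed with the
package (`inst/scripts/coremod`), with subcommands `cluster`, `expand`,
`resolve`, `score`, `eval`, `comorbid` and `synth`.

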