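---
title: "Core disease module identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core disease module identification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Protein interaction, co-expression, signaling and homology networks are
highly modular: groups of densely interconnected genes tend to share
function, and disease phenotypes arise from the dysfunction of such
groups. Standard community detection, however, adapts poorly to these
networks. They are dense and noisy; optimizing global quality functions
yields a few giant communities anchored on high-degree nodes, while
biologically meaningful *disease modules* are small (roughly 3–100
genes, averaging around 60). `coremod` implements a stack of methods for
extracting small, structurally strong **core modules** from weighted
undirected networks and for judging them against GWAS gene scores:
quality measures, baseline partitioners, four core-extraction
frameworks, personalized-PageRank (PPR) seed expansion, resolution of
overlapping covers, an enrichment scorer, trait comorbidity networks,
and a synthetic benchmark generator so the whole pipeline is testable
without any external download.

## Data model

Graphs are undirected, vertex-named `igraph` objects with a strictly
positive `weight` edge attribute; `read_weighted_edgelist()` enforces
simplicity (no self-loops, no duplicate pairs; directed inputs are
symmetrized by keeping the maximum weight per unordered pair, since every
downstream formula assumes a symmetric adjacency). The weighted degree
is `d_i = sum_j A_ij` and `e` denotes total edge weight, so
`sum_i d_i = 2e`. A *partition* is a named integer vector with
contiguous labels `1..k`; a *cover* is a named list of node sets that
may overlap; gene scores are a genes-by-traits matrix of p-values in
(0, 1].

`sparsify()` implements the usual preprocessing for noisy confidence-
weighted networks: a global weight threshold. The default mode keeps
`w >= mu - 2*sigma` (the literal "two standard deviations below the
mean" reading, with the population standard deviation); the
`mean_plus_ksd` and `quantile` modes are provided because on
heavy-tailed weight distributions `mu - 2*sigma` can fall below the
minimum weight and remove nothing. Thresholds are computed per network,
and isolated nodes are retained.

## Quality measures

For a community `c` with internal weight `W_int` (both endpoints
inside), cut `cut(c)` (one endpoint inside) and volume
`vol(c) = sum_{i in c} d_i = 2*W_int + cut`:

* **Modularity** (resolution `gamma`, default 1):
  `Q(c) = (1/2e) * sum_{i != j in c} (A_ij - gamma * d_i d_j / 2e)`.
  Self-pairs are excluded from the null term. This differs from the
  Newman convention that includes `i = j`: with all nodes of a d-regular
  graph in one community the score here is `sum(d^2)/(2e)^2 = 1/n`, not
  1. Partition modularity is the sum over communities; a single node set
  is scored as one community against the whole graph's `2e` (not the
  induced subgraph's — a choice that matters for the expansion stop rule
  below).
* **Conductance**: `cut(c) / min(vol(c), vol(complement))`, in [0, 1],
  0 for a whole component, symmetric under complementation. The
  denominator uses volumes: defining the denominator through `W_int`
  instead would push scores above 1 on cliques.
* **CEIL**: internal density `W_int / C(n_c, 2)` times separability
  `W_int / (W_int + cut)`; singletons and edgeless sets score 0; an
  isolated clique scores 1.
* **Core score** (per node, within a module): outgoing weight divided by
  internal weight. Lower ranks better; a node with no internal edges
  scores `Inf` so it is pruned first.

All formulas are weighted and reduce to counting forms on unweighted
graphs. The test suite checks all four against independent double-loop
evaluation on exhaustively enumerated modules of small random graphs at
`1e-12` tolerance.

## Baseline partitioners

* `louvain_partition()` — multilevel greedy modularity maximization,
  with the *resistance* `R` interpreted as the resolution multiplier on
  the null term (the only standard one-parameter family consistent with
  a stated range [0.1, 1] whose effect is to control module size). It is
  backed by `igraph::cluster_louvain(resolution = R)`; a seed fixes the
  randomized vertex order.
* `mcl_partition()` — Markov clustering: column-stochastic transition
  matrix with unit self-loops, alternating expansion (matrix power 2)
  and inflation (elementwise power `I`, column renormalization), entries
  below `1e-8` pruned per iteration, convergence when the maximum entry
  change drops below `1e-6`. Clusters are the weakly connected
  components of the nonzero pattern of the limit matrix, which also
  resolves nodes reachable from several attractors. The inflation grid
  used throughout is `I = 2..9`.
* `ceil_partition()` — greedy local moving (deterministic sweeps in
  lexicographic node order, no aggregation phase) maximizing the
  size-weighted network objective `sum_c (n_c/n) * CEIL(c)`; it has no
  hyperparameter. On two bridged cliques it provably attains the
  exhaustive-search optimum (checked over all 4140 partitions of 8
  nodes in the tests).

## Core-module frameworks

**Consensus ensembles.** Each of `r` base clusterings assigns every node
a label; labels are qualified by the clustering index so labels from
different runs never collide. For a node pair agreeing in `a` of `r`
clusterings the qualified Jaccard similarity of their assignment vectors
is `a/(2r - a)` (1 exactly when the pair co-occurs everywhere); pairs
above the 0.5 threshold are linked, similarity as weight, and the
consensus network is clustered with Louvain; nodes isolated in the
consensus become singletons.

A design note on the default: at threshold 0.5 the qualified form
requires agreement in more than `2r/3` of the base runs. With the full
baseline grid (Louvain at ten resistances, MCL at eight inflations,
CEIL) that bar is unreachable on sparse communities — high-inflation MCL
and CEIL legitimately shatter them, capping agreement below the bar even
when every Louvain run concurs — and the consensus collapses into
fragments. `ensemble_cluster()` therefore defaults to the simple
matching form `a/r` (the co-association/evidence-accumulation
convention: link pairs co-clustered in a majority of runs), and exposes
`consensus = "qualified"` for the stricter variant.
`consensus_network()` itself keeps the qualified form as its default.

**Perturbation consensus.** To find modules robust to the noise inherent
in interaction data, the graph is perturbed `iterations` times (default
100; the evaluation suites use the scaled-down 20) by dropping
`floor(drop_frac * |E|)` edges uniformly at random (default 1%,
weights ignored), each copy is clustered with Louvain, and the
partitions are combined through the consensus network.

**Reclustering.** `recluster_large()` repeatedly applies Louvain to the
induced subgraph of any module above `max_size` (default 100) and
replaces it by the sub-partition; modules the sub-clusterer refuses to
split are kept and marked unsplittable. The operation is refinement-only
— it never merges nodes across input modules.

**Minimum-outgoing cores.** For modules above `size_trigger` (default
100), members are ranked by core score ascending (ties: higher internal
weight, then node id) and the best `core_size` nodes are kept. The
default core size of 60 reflects the empirical average disease-module
size; both values are configuration, not constants.

## Seed selection and PPR expansion

Three seed-selection strategies: *disease seeds* (genes below a p-value
cutoff — conventionally `1e-4`, or `1e-6` for a stricter panel — in at
least one trait, union semantics), *HITS hubs* (power iteration of the
hub/authority updates to `1e-10`; on an undirected graph this is the
principal eigenvector of `A^2`), and *spread hubs* (greedily take the
highest-weighted-degree unmarked node, then mark it and its neighbours,
so seed neighbourhoods never overlap).

`ppr()` computes approximate personalized PageRank by residual pushes: a
push at `u` moves `alpha * r_u` to the score and distributes
`(1 - alpha) * r_u` over the incident edges in proportion to weight,
until every residual satisfies `r_u < eps * d_u`. Mass is conserved
exactly (`sum(score) + sum(residual) = 1`), a degree-zero node absorbs
its residual, and the result is schedule-independent up to `eps` (the
tests cross-check against an independent personalized PageRank solver).
The teleport `alpha = 0.85` and `eps = 1e-5` defaults are conventional
PPR practice — neither is dictated by the method — and both are
configurable and echoed in run configs.

`expand_seed()` ranks reachable nodes by degree-normalized PPR score
(`score/d`, the standard sweep ordering; raw-score ranking via
`normalize = FALSE`), grows a prefix from the seed one node at a time up
to `max_size = 100`, records single-community modularity after every
addition, and returns the modularity-maximal prefix of size at least
`min_size = 3` (the lower end of the disease-module size range; seeds
that cannot reach it are rejected and reported). Prefix modularity is
computed against the whole graph's `2e`; the growing-subgraph
normalization would make prefixes incomparable across sizes.
`expand_all()` runs every seed and deduplicates identical modules into a
cover.

## Resolving overlaps

`base_communities()` splits a cover into the *base* (nodes with exactly
one label) and the *overlap* (two or more). Three assignment methods
return a partition: random (uniform among the node's own candidate
modules — keeping assignment local; a `global` option relaxes this),
independent minimum-conductance (each overlap node joins the candidate
community whose conductance *after* inclusion is minimal —
before-inclusion conductance would not depend on the node at all), and
iterative minimum-conductance: sequential assignment with recomputation
after every placement, then reassignment phases (extract, re-place by
minimum conductance) until a phase moves no node. Nodes are processed in
lexicographic order for determinism; the reassignment phases are the
mechanism that removes the order bias. At convergence the partition is
1-stable — no single overlap node can move to another candidate and
obtain a lower receiving-community conductance — and on the overlapping
benchmark convergence takes a few phases (the suite requires at most 5).

## Enrichment scoring

`enrich_modules()` is a deliberately simple module scorer: for each
(module, trait) pair the member genes' p-values are combined with
Fisher's method (`-2 * sum(log p)` against chi-square with `2k` degrees
of freedom, where `k` is the module size; genes missing from the table
or `NA` for a trait are imputed `p = 1`, which keeps the test
conservative), followed by Benjamini–Hochberg adjustment across all
pairs and flagging at the configured FDR (default 5%). It performs no
SNP-to-gene aggregation, no linkage-disequilibrium correction and no
gene fusion — full pathway-scoring pipelines do — so externally computed
calls can be imported through `as_enrichment()` and flow into the same
reporting. The suite verifies the flagged set equals the exact BH
step-up set, that the flag rate under a uniform null stays within
binomial error of the FDR level, and that a planted `Beta(0.1, 1)`
signal is detected with high power.

Reporting arithmetic is separate and exact: `hit_ratio()`
(enriched/predicted), `method_score()` (total enriched modules across
networks), `graph_density()`, `overlap_counts()`, and
`comorbidity_network()`, which links every pair of traits jointly
enriching a module, counts co-occurrences, and keeps the top
`ceiling(top_frac * n_edges)` edges by count (ties at the cutoff all
kept).

## The synthetic benchmark

`planted_partition()` draws independent within-block edges with
probability `p_in` (weights Uniform(0.6, 1)) and between-block edges
with probability `p_out` (weights Uniform(0.1, 0.5)), echoing the
semantics of confidence-weighted interaction networks where true
interactions carry high scores. `p_in` may vary per block to plant
communities of unequal structural strength.
`overlapping_benchmark()` adds designated overlap nodes per adjacent
block pair, wired into both blocks at `p_in`, making the truth a cover.
`synth_gwas()` gives genes of each trait's causal modules p-values from
`Beta(a, 1)` (CDF `x^a`; at the default effect `a = 0.1` a causal gene
passes `1e-4` with probability `(1e-4)^0.1 ≈ 0.398`) and everything else
Uniform(0, 1) — the closed-form CDF is what makes the calibration
testable.

The default study conditions used across the evaluation suites are 4
blocks of 20 (recovery) or 25 (expansion), `p_in = 0.3`,
`p_out = 0.01`, 3 traits, with 10–20 simulation seeds per claim; the
enrichment calibration uses 200 modules by 5 traits. What the generator
does *not* emulate: power-law degree distributions, the heavy size
heterogeneity of real interaction networks, correlated gene scores from
linkage disequilibrium, and module-size diversity. Passing tests
therefore demonstrate correctness of the machinery and sane behavior
under the planted model, not performance on interactome-scale data.

## Numerical and evaluation choices

* Benchmark-scale resolution: planted-recovery evaluations run Louvain —
  including the per-copy clusterings inside the perturbation framework —
  at `gamma = 1`. The protocol value `R = 0.1` is tuned to real
  interactome-scale networks; at 80 nodes it down-weights the null term far
  enough to hit the Louvain resolution limit and merge planted block
  pairs in roughly a quarter of realizations, a property of the
  objective rather than of the consensus machinery. `R = 0.1` remains
  the package default.
* Seed-fraction analyses subsample nested seed sets (one shuffle per
  simulation, prefixes at 10/50/80/100%), so the recovered-module count
  is monotone per run rather than only in expectation.
* Ties are broken lexicographically everywhere a deterministic order is
  needed (seed ranking, core ranking after internal weight, assignment
  order, LCC selection by smallest member).
* Degenerate inputs: empty graphs are legal for I/O and sparsification
  but fatal for clustering; modules of isolated nodes have undefined
  conductance (error); a cover in which every node overlaps has no base
  to assign into (error); p-values are clamped at `1e-300` before
  logging.
* MCL tolerances: convergence `1e-6` on the maximum entry change,
  pruning at `1e-8`, self-loop weight 1.

## Limitations

The enrichment scorer is a stand-in with the same interface and
decision rule as pathway-scoring pipelines, not a reimplementation of
one. The partition-based methods inherit Louvain's resolution behavior.
PPR expansion is local by construction: a seed whose neighbourhood
spans several planted modules produces one module per the modularity
stop rule, not several. The synthetic generator's homogeneous blocks
make recovery easier than on real heterogeneous networks; results on it
bound correctness, not real-world performance.
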