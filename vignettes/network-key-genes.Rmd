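---
title: "Prioritizing key disease genes in consensus interaction networks"
author: "NetKeys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing key disease genes in consensus interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NetKeys)
library(igraph)
```

# The problem

Disease-associated genes rarely act alone: their proteins participate in an
interaction network whose structure decides which perturbations matter.
`NetKeys` implements a complete, offline-testable pipeline for prioritizing
key genes in such networks, built around protein-protein interaction (PPI)
data of the kind exported by STRING, BioGRID, DIP, IntAct or MINT for a seed
list of disease genes (the motivating use case is an amyotrophic lateral
sclerosis interactome, but nothing in the package is disease-specific):

1. **Consensus construction** — an interaction is trusted only when at
   least two independent source databases report it.
2. **Topological characterization** — degree distribution, clustering,
   neighborhood connectivity and three centralities, with power-law fits on
   log-log axes and a regime classification of the network.
3. **Key-node selection** — hubs (top 1% by degree) and bottlenecks (top 1%
   by betweenness), their intersection (bottleneck-hubs, Bn-H), and
   single-node knockout experiments that probe the centrality-lethality
   rule.
4. **Module detection** — a from-scratch reimplementation of the MCODE
   molecular-complex-detection algorithm (vertex weighting, seeded
   expansion, haircut/fluff post-processing, density x size scoring).
5. **Cross-talk** — edge counts between each bottleneck-hub and each
   module.
6. **Annotation** — hypergeometric over-representation of module gene sets
   against GMT term collections, and disease-class percentage profiles from
   gene-disease tables.

A seeded synthetic-data module generates inputs with planted structure for
every stage, so the whole pipeline is exercised without any database access.

# The consensus network

Interaction records are unordered gene pairs tagged with a source label.
`buildConsensus()` keeps a pair as an edge when it is reported by at least
`minSources` *distinct* sources (default 2); duplicate records within one
source count once, self-loops are removed before counting, and nodes left
without edges are dropped. The result is a simple undirected graph `G(N, E)`
carried by the `ConsensusNetwork` S4 class, with the per-edge support count
as an edge attribute.

Support counting is deliberately the only evidence rule: source-specific
confidence scores (e.g. STRING combined scores) are not interpreted, and no
confidence cutoff is applied before the two-database rule. Consensus is
monotone — raising `minSources` can only remove edges.

```{r consensus}
sim <- generateMultisourceInteractome(nGenes = 60, nSources = 5,
                                      nTrueEdges = 150, seed = 7)
net <- buildConsensus(sim$records, minSources = 2)
net
numEdges(net) == nrow(sim$truth)
```

# Topological statistics

For each node the package reports:

* degree $k$;
* clustering coefficient $C_i = 2 m_i / (k_i (k_i - 1))$, where $m_i$
  counts edges among the node's neighbors ($C_i = 0$ for $k_i < 2$);
* neighborhood connectivity $C_N$, the mean degree of the neighbors;
* betweenness $C_B(v) = \sum_{i \ne j \ne v} \sigma_{ij}(v) / \sigma_{ij}$,
  normalized by $(N-1)(N-2)/2$ so values lie in $[0, 1]$;
* closeness, computed per connected component as $(n_c - 1) / \sum_j
  d_{ij}$. The textbook form with a global-$N$ numerator is unbounded on
  disconnected graphs, so the component-wise convention is used and
  recorded here as a deliberate choice;
* eigenvector centrality, the principal eigenvector of the adjacency
  matrix ($A v = \lambda v$), computed by power iteration on $A + I$ — the
  shift guarantees convergence on bipartite components, where plain power
  iteration oscillates between the $\pm\lambda$ eigenspaces. Iteration runs
  to an elementwise tolerance of 1e-10 (at most 1000 steps) and the result
  is validated against the residual $\lVert A v - \lambda v \rVert_\infty <
  10^{-8}$. The vector is nonnegative with unit L2 norm over the largest
  connected component; other nodes get 0 with a warning.

Degree-averaged curves (`degreeCurve()`) average a statistic over all nodes
sharing a degree; nodes with $k < 2$ are excluded from the clustering curve
because $C$ is undefined there. No logarithmic binning is applied.

## Power-law fits and regimes

`fitPowerLaw()` is an ordinary least-squares fit of $\log_{10}(\text{value})$
on $\log_{10}(k)$; the reported exponent is minus the slope, together with
the slope's standard error and the Pearson correlation $r$ of the
log-transformed points. This regression-style estimator is the one used with
per-degree curves in network biology tools; maximum-likelihood tail fitting
(Clauset-style) is intentionally out of scope.

On sampled degree distributions the high-degree tail consists of degrees
observed exactly once, forming a flat plateau at $1/N$ that biases the
regression slope toward zero. `fitPowerLaw(curve, minCount = 2)` censors
that plateau by restricting the fit to degrees carried by at least two
nodes; the default (`minCount = 1`) uses every positive point.

`classifyRegime()` maps the $P(k)$ decay exponent $\gamma$ to the standard
interpretation: $\gamma < 2$ — hierarchical/modular organization in which
modules dominate; $2 \le \gamma \le 3$ — scale-free topology with smaller
hubs integrated under a few large ones; $\gamma > 3$ — hubs unrelated, most
scale-free character lost.

```{r topology}
hs <- generateHierarchicalScaleFree(n = 2000, m = 3, triadProb = 0.8,
                                    seed = 7)
g <- igraph::graph_from_data_frame(hs, directed = FALSE)
fit <- fitPowerLaw(degreeDistribution(g), minCount = 2)
fit
classifyRegime(fit@exponent)
```

# Hubs, bottlenecks and knockouts

`selectTopFraction()` takes the top `floor(q * N)` nodes by a metric
(default `q = 0.01`): on a 1949-node network that is 19 nodes — the floor
rule, not ceiling, reproduces that count. Ties at the rank boundary are
broken by symbol, ascending, so selection is deterministic.
`identifyBottleneckHubs()` intersects the two rankings into bottleneck-hubs
and the two set differences.

`knockout()` removes one node, recomputes the degree distribution and
betweenness on the remainder, and summarizes the perturbation as the change
in component count, the number of edges removed (the intact degree) and the
mean/max absolute betweenness change over surviving nodes. Knockouts in a
screen are independent — each starts from the intact network — matching the
one-at-a-time design of computational knockout experiments. The
perturbation summaries are continuous scores; no significance call is made,
because no accepted threshold exists for "significant" topological change.

# MCODE module detection

The three-stage algorithm is implemented from scratch:

1. **Weighting.** For node $v$, take the subgraph induced on $v$ plus its
   neighbors, find its highest $k$-core, and set
   $w(v) = k_{\max} \times \text{density}$ of that core subgraph
   (density $= 2E/(n(n-1))$).
2. **Prediction.** Unvisited nodes seed complexes in weight-descending
   (then symbol-ascending) order; a breadth-first expansion admits an
   unvisited neighbor when its weight **exceeds**
   $w(\text{seed}) \times (1 - \text{nodeScoreCutoff})$, up to `maxDepth`
   steps from the seed. Admitted nodes are marked visited, so complexes are
   disjoint.
3. **Post-processing.** Complexes without a 2-core are discarded; haircut
   iteratively removes members with fewer than two internal neighbors until
   a fixpoint (iteration rather than a single pass makes the operation
   idempotent); fluff, off by default, may then add boundary nodes whose
   closed-neighborhood density exceeds 0.1.

Defaults are the standard tool's: node score cutoff 0.2, haircut on, fluff
off, k-core 2, max depth 100. Fluff defaults to off even though a density
cutoff is always displayed among the parameters, because disjoint modules
are what make downstream per-module accounting additive. The module score
is density x size; published M-scores display with two decimals obtained by
truncation — `formatScore(4.375)` is `"4.37"`, and that convention (not
rounding) is what reproduces published score tables. `selectModules()`
keeps scores strictly above 4 by default.

```{r mcode}
plant <- generatePlantedComplexes(nNodes = 100, bgDensity = 0.02,
                                  complexes = list(c(8, 0.9), c(10, 0.9)),
                                  seed = 4)
pg <- igraph::graph_from_data_frame(plant$edges, directed = FALSE)
mods <- mcode(pg)
modulesTable(mods)[, c("seed", "n", "edges", "scoreDisplay")]
```

# Cross-talk and annotation

`crosstalkMatrix()` counts, in the full consensus network, the edges
between each bottleneck-hub and each module's members. A hub that is itself
a module member contributes its edges to the *other* members only
(self-exclusion) — with that convention a member hub's cell is an edge
count, never an artifact of membership. Rows are ordered by total,
descending. With fluff off the modules are disjoint, so a row total can
never exceed the hub's degree.

`enrich()` performs the hypergeometric over-representation test,
$P(X \ge \text{overlap})$ with the consensus-network node set as the
default universe, each term intersected with the universe first.
Benjamini-Hochberg controls the FDR across terms; it replaces proprietary
ordering-based corrections used by web services, a substitution recorded in
the result's `adjustMethod` attribute. Significance is called at adjusted
$p \le 0.05$.

`diseaseClassProfile()` reports, per gene and per module, the percentage of
distinct associated diseases in each disease class (MeSH-style). A disease
tagged with several classes counts once in each class's numerator, so
percentages may sum above 100 — that is the stated convention, not a bug.
Both granularities are emitted because published per-gene and per-module
statements mix the two.

# The synthetic generators

The generators define the conditions under which the pipeline is tested:

* `generateMultisourceInteractome()` — every true edge is force-emitted
  into two distinct sources (plus others at `pEmit = 0.4`), so consensus at
  `minSources = 2` recovers the planted truth *exactly by construction*;
  decoys live in exactly one source each and can never reach consensus.
  Without forced double emission recovery would hold only in probability
  and the contract would be flaky.
* `generateHierarchicalScaleFree()` — growth with preferential attachment
  plus triad closure (`triadProb = 0.8`), producing heavy-tailed $P(k)$ and
  a clustering curve that decays with degree; `m = 1` degenerates to a
  tree.
* `generatePlantedComplexes()` — disjoint dense blocks (sizes >= 3, stated
  internal densities) over a sparse background (default 0.02). Pairs
  spanning two different planted blocks are never wired: a single random
  inter-block edge would legitimately cause the seeded expansion to merge
  two dense blocks into one complex, so non-adjacency of plants is part of
  the construction that guarantees recovery. Cross-talk to a plant flows
  through background nodes only.
* `generateAnnotations()` — a planted term covering 80% of a designated
  subset against a 5% background inclusion rate, plus random terms; disease
  classes are assigned at *exact* per-gene proportions (default 60/40), so
  profile assertions are deterministic.

Every generator is a pure function of its arguments and seed (RNG state is
saved and restored), and file output is byte-identical across runs.

What the generators do **not** emulate: database-specific confidence-score
distributions, MITAB evidence codes, study bias in annotation coverage, or
the heavy overlap structure of real complex catalogs. Passing tests
therefore demonstrate algorithmic correctness under controlled topology,
not robustness to real-data noise.

# Numerical choices and edge cases

* Symbols are uppercased and whitespace-stripped; aliasing happens only
  through a user-supplied map (chains are followed; conflicts and cycles
  are errors naming the alias).
* Degenerate inputs fail loudly: empty seed lists, zero parseable edge
  rows, an empty consensus, fits with fewer than three usable points.
* Ties are always broken lexicographically (rank boundaries, MCODE seed
  order, module ordering) so every result is reproducible.
* $\sum_k P(k) = 1$ is enforced to 1e-12 by the `DegreeCurve` validity
  method.
* Eigenvector centrality on a disconnected graph is defined on the largest
  component, 0 elsewhere, with a warning rather than silence.
* Problem sizes in the test suite — 200 random graphs of up to 10 nodes
  against brute-force oracles, a 5000-node growth model, 100-node planted
  backgrounds — were chosen as the smallest instances at which each
  property is informative; the whole suite runs in well under a minute.

# Known limitations

* The regression exponent estimator is biased on undersampled tails (hence
  `minCount`); it is a descriptive fit, not a tail estimator.
* MCODE recovery of planted near-cliques at density 0.9 is not guaranteed
  for *every* random instance — occasionally a member's weight falls below
  the seed threshold and the complex is recovered partially; the tests
  document behavior at fixed seeds.
* Betweenness recomputation in `knockoutScreen()` is exact, so screening
  all nodes of very large networks is quadratic-ish in practice; screen the
  selected key nodes, not the whole network.
* No live database access of any kind; inputs are files in the documented
  dialects.
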