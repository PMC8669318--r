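# NetKeys

Key-gene prioritization in consensus protein–protein interaction (PPI)
networks, for systems-biology analysts who start from a disease seed-gene
list and per-database interaction exports (STRING/BioGRID/DIP/IntAct/MINT
style TSV or minimal PSI-MITAB) and want the full topology-to-annotation
pipeline reproducible offline.

## What it computes

- **Consensus network** `G(N, E)`: an unordered gene pair is an edge iff it
  is reported by ≥ 2 distinct source databases (configurable); simple
  graph, per-edge support counts, isolated nodes dropped.
- **Topology**: per node, degree *k*, clustering coefficient
  `C = 2m/(k(k−1))`, neighborhood connectivity `C_N` (mean neighbor
  degree), betweenness `C_B = Σ σ_ij(v)/σ_ij` normalized to [0, 1],
  component-wise closeness `C_C = (n_c−1)/Σ d_ij`, and eigenvector
  centrality `A v = λ v` (unit L2 norm, power iteration). Degree-averaged
  curves are fitted on log–log axes by least squares (`P(k) ~ k^−γ`,
  `C(k) ~ k^−α`, ...) with exponent, standard error and Pearson *r*; the
  exponent classifies the regime (γ < 2 hierarchical/modular, 2–3
  scale-free, > 3 hub-independent).
- **Key nodes**: hubs = top `floor(0.01·N)` by degree, bottlenecks = same
  by betweenness, bottleneck-hubs (Bn-H) = the intersection; systematic
  single-node knockouts quantify each Bn-H's perturbation (Δcomponents,
  edges removed, mean/max |ΔC_B|) per the centrality-lethality rule.
- **MCODE modules** (re-implemented): closed-neighborhood k-core vertex
  weighting, seeded expansion at node-score cutoff 0.2, haircut/fluff
  post-processing, M-score = density × size with 2-decimal truncated
  display, modules kept at score > 4.
- **Cross-talk**: Bn-H × module edge-count matrix with row totals and
  membership flags (a member hub counts edges to other members only).
- **Annotation**: hypergeometric over-representation of module gene sets
  against GMT collections (BH-adjusted, α = 0.05) and disease-class
  percentage profiles from gene–disease–class tables.
- **Synthetic data**: seeded generators for multi-source interactomes with
  an exactly recoverable planted truth network, hierarchical scale-free
  graphs, planted dense complexes and planted-enrichment annotation
  tables.

## Worked example

```r
library(NetKeys)

# five simulated source databases over 60 genes, 150 true interactions
sim <- generateMultisourceInteractome(nGenes = 60, nSources = 5,
                                      nTrueEdges = 150, seed = 7)
net <- buildConsensus(sim$records, minSources = 2)
net
#> ConsensusNetwork with 59 nodes and 150 edges
#>   minimum source support: 2
#>   support range: [2, 5]
```

All 150 consensus edges are exactly the planted true interactions; the
single-source decoys were rejected. Rank the nodes and intersect the top
5% by degree and betweenness:

```r
metrics <- nodeMetrics(net)
sel <- selectKeyNodes(net, q = 0.05, metrics = metrics)
sel
#> RankedSelection: top 2 per metric (fraction 0.05)
#>   bottleneck-hubs: 1
#>   hub-only: 1
#>   bottleneck-only: 1
knockoutScreen(net, bottleneckHubs(sel))
#>    node edgesRemoved nComponentsDelta meanAbsDeltaCB maxAbsDeltaCB
#> 1 G0004            9                0    0.005014738    0.01848938
```

`G0004` is both a hub and a bottleneck; knocking it out removes its 9
edges and shifts surviving betweenness by up to 0.018 without
disconnecting the network. Module detection on a planted benchmark:

```r
plant <- generatePlantedComplexes(100, bgDensity = 0.02,
                                  complexes = list(c(8, 0.9), c(10, 0.9)),
                                  seed = 4)
pg <- igraph::graph_from_data_frame(plant$edges, directed = FALSE)
modulesTable(mcode(pg))[, c("seed", "n", "edges", "density", "scoreDisplay")]
#>    seed  n edges   density scoreDisplay
#> 1 G0014 10    41 0.9111111         9.11
#> 2 G0004  8    27 0.9642857         7.71
#> 3 G0064  3     3 1.0000000         3.00
```

Both planted complexes are recovered exactly (scores 9.11 and 7.71; the
3-node triangle falls below the score-4 cut). M-scores follow the
density × size rule with truncated display:

```r
formatScore(scoreComplex(11, 44))
#> [1] "8.80"
```

Example data under `inst/extdata/` (`als_hubs.tsv`, `als_bottlenecks.tsv`,
`als_crosstalk.tsv`, `als_modules.tsv`) carry the published hub/bottleneck
rankings, module sizes and cross-talk counts of a 1949-node ALS
interactome for the worked checks in the test suite.

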