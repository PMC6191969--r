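---
title: "Frontier-based traversal of biological networks: methods and design"
author: "frontierNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontier-based traversal of biological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontierNet)
```

## The problem

Biological networks — protein–protein interaction maps, homology networks,
gene coexpression graphs — are analysed with a small set of graph
primitives: how far apart are two nodes (breadth-first search), what is the
cheapest route under edge weights (single-source shortest paths), and which
part of a directed network is mutually reachable (strongly connected
components). frontierNet implements these three kernels with explicit
*frontier* semantics — at every iteration an ordered, duplicate-free set of
active vertices drives the next round of work — over a compressed sparse
row (CSR) graph built from a plain three-column edge table. On top of the
kernels it provides the workflows these primitives exist for: confidence
thresholding of weighted interaction networks, Pearson coexpression-network
construction, extraction of the component containing a seed gene, and mean
shortest-path statistics inside versus around that component.

## Graph representation

A graph enters as a coordinate list: a data frame of `(from, to, weight)`
records (`edgeTable()`, or `readEdgeCsv()` for files with arbitrary string
labels, mapped to contiguous 1-based ids in order of first appearance).
`buildCSR()` converts it to CSR: an `offsets` array indexing each vertex's
slice of the concatenated `targets`/`weights` arrays. Three representation
choices matter downstream:

* **Canonical adjacency order.** Within each vertex's slice, targets are
  sorted ascending, ties between parallel edges by ascending weight. The
  representation of an arc multiset is therefore unique, which makes graph
  equality, transposition round-trips and golden tests exact.
* **Parallel edges and self-loops are kept.** Collapsing parallel edges
  (say, to their minimum weight) would silently change shortest-path
  semantics; BFS is insensitive to them, and Bellman-Ford simply relaxes
  all of them. Self-loops never affect BFS/SSSP results.
* **Undirected graphs are stored symmetrically** (two arcs per record,
  self-loops once), so every traversal kernel is written once, for
  directed CSR, and undirected inputs come along for free. This mirrors
  how undirected interaction networks are usually fed to directed kernels.

## Breadth-first search

`bfsMulti()` is level-synchronous: frontier `F1` holds all and only the
vertices at depth `k`; their unvisited out-neighbors form `F2`, which is
deduplicated (a hard guarantee here — when several frontier vertices reach
the same neighbor in one step, it enters the next frontier exactly once),
assigned depth `k + 1`, and swapped in for the next level. Since the
visited set strictly grows, the loop terminates within `|V|` steps. The
result is an `s × |V|` depth matrix, one row per source; unreachable
vertices carry the sentinel `Inf`, serialized as `"inf"` in TSV output.
Frontiers are emitted in ascending vertex order: parallel emission order is
meaningless, and a canonical order makes runs byte-reproducible.

## Shortest paths (Bellman-Ford with frontiers)

`sssp()` keeps the Bellman-Ford structure but does work only where it can
matter: the frontier after each pass contains all and only the vertices
whose tentative distance changed in that pass, and only their out-arcs are
relaxed next. Within one pass, frontier vertices are swept in ascending id
order with live distance reads (Gauss–Seidel style); this reaches the same
fixed point as a frozen-snapshot sweep, never in more passes — the fixed
point, not the pass count, is the contract. Ties between equal-cost
predecessors resolve to the last strict improvement in the canonical sweep
order, which is implementation-defined but deterministic.

Negative arc weights are accepted. With no negative cycle reachable from
the source, the fixed point arrives within `|V| − 1` passes, so a frontier
still alive after `|V|` passes proves a reachable negative cycle; `sssp()`
raises an error then, because no shortest-path answer is well defined.
Distances come with a predecessor matrix (optional), from which
`reconstructPath()` rebuilds any shortest path; a source's own
predecessor, and that of an unreached vertex, is `NA` (an empty field in
TSV output).

## Strongly connected components

`scc()` is the classical three-phase decomposition:

1. **Trimming** (`trimTrivial()`): a vertex with no active successor or no
   active predecessor cannot lie on a cycle, so it is a singleton
   component. Removal cascades to a fixed point; a DAG is fully resolved
   by this phase alone. A self-loop counts as neither an active successor
   nor predecessor here — otherwise a vertex whose only cycle is its own
   loop would never be trimmed despite being a trivial component.
2. **Forward–backward** (`forwardBackward()`): from a pivot, the forward
   and backward reachability closures within the current subset are
   intersected; the intersection is the pivot's component, and the three
   residues (forward-only, backward-only, untouched) are SCC-closed, so
   they recurse independently. The pivot heuristic maximizes the product
   of within-subset out- and in-degree (ties to the smallest id): a
   high-degree pivot tends to classify more vertices per round. Each
   subset is trimmed before processing — sound on any SCC-closed set.
   How many rounds to run is genuinely open in the three-phase scheme;
   `fbRounds` (default 1) exposes it, and correctness is independent of
   it by construction and by test.
3. **Coloring** (`coloringDecompose()`): each remaining vertex starts with
   its own id as color; the maximum color propagates along arcs among
   active vertices to a fixed point; every vertex that kept its own color
   is a pivot whose backward closure within its color class is one
   component. The largest active id always keeps its color, so each round
   removes at least one component and the loop terminates.

Component ids are canonicalized to each component's smallest member, so the
output is independent of how work happened to be split across phases.

## Network-analysis workflows

* `scoreFilter(edges, minScore)` keeps records with weight ≥ threshold and
  leaves the vertex universe intact (isolated vertices survive), so one
  network yields a family of sparser, higher-confidence networks.
* `correlationNetwork(expr, threshold, mode)` computes all pairwise
  Pearson correlations between gene rows and emits edges weighted by r.
  Both sign conventions are offered because published coexpression
  pipelines differ: `absolute` (default) connects strongly correlated
  pairs regardless of direction; `signed` keeps positive correlations
  only. Zero-variance genes have undefined r and never form edges; genes
  with missing values are dropped listwise — the simplest deterministic
  policy, with imputation deliberately out of scope. The threshold is a
  required argument: there is no defensible universal default.
* `transformWeights()` maps similarities to distances (`1 − |r|` for
  correlations, `maxScore − w` for confidence scores) as an explicit step,
  because path length over raw similarities is meaningless and the right
  transform is a modelling decision the user should see.
* `subnetworkWithSeed()` extracts the component containing a seed gene and
  `meanShortestPath()` averages all finite ordered-pair distances
  (unreachable pairs are counted but excluded from the mean). Comparing
  the mean within the seed's subnetwork against the whole graph asks
  whether the seed's neighborhood is more tightly knit than background.
  Note the guaranteed relation is per ordered pair — an induced
  subnetwork's distance can only be ≥ the full graph's, since paths may
  leave the subnetwork — while the two *means* run over different pair
  sets and need not be ordered.

## Synthetic data: what it emulates, and what it does not

All tests and the reproduction script run on generated inputs; every
generator takes an explicit integer seed, uses R's Mersenne–Twister stream
locally, and restores the caller's RNG state, so identical configurations
are byte-identical.

* `genErdosRenyi(n, p)`: the null topology for oracle testing; every pair
  independent with probability `p`.
* `genStringLike(n, m)`: preferential attachment with integer scores
  uniform in 1–999 — heavy-tailed degrees and a confidence-score scale
  like curated interaction databases. It does not reproduce any real
  database's degree distribution or score semantics; it provides the
  right *shape* of input (hubs, score thresholds that sparsify) at desk
  scale. Defaults used in the reproduction script: n = 2000, m = 3,
  giving ~6,000 edges.
* `genPlantedScc(blockSizes)`: blocks wired as directed Hamiltonian
  cycles plus random intra-block arcs (`pIntra = 0.15`), inter-block arcs
  only forward in block order (`pInter = 0.05`) — the block partition is
  provably the component partition, giving ground truth without an
  oracle.
* `genExpression(nSamples, assignments, mixing)`: module genes load on a
  shared latent factor with coefficient `mixing` plus independent
  Gaussian noise, so within-module correlation is `mixing²` in
  expectation (exactly 1 at `mixing = 1`). The acceptance setting —
  two 10-gene modules, 30 background genes, 100 samples, `mixing = 0.9`
  (within-module r ≈ 0.81, about 9 standard errors above a 0.5
  threshold) — makes clean recovery the *expected* outcome, which is the
  point: it verifies the pipeline, not the hardness of real data. Real
  expression data have correlated backgrounds, heavy tails, batch
  effects and missingness that these tests deliberately do not model, so
  passing them shows the machinery is correct, not that any particular
  threshold is right for a real dataset.

## Numerical and interface choices

* Vertex ids are 1-based and contiguous internally, the R convention;
  files may use arbitrary labels, mapped by first appearance and carried
  through to all outputs.
* Distances compare exactly for BFS (integer hops in doubles) and to
  1e-9 relative tolerance for weighted paths in tests; the kernels
  themselves use exact `<` comparisons, so the fixed point is unique for
  given inputs.
* `Inf` is the unreachable sentinel (`"inf"` in TSV); `NA` is the absent
  predecessor (empty TSV field). Both round-trip through the writers.
* The command-line layer (`cliMain()`, wrapped by
  `inst/cli/frontiernet.R`) is a pure function of input files, flags and
  seed; re-running any subcommand reproduces outputs byte for byte.
* Problem sizes in the test suite (graphs up to n = 300 for component
  checks, n = 200 for path checks, 100–200 replicate graphs per
  property) were chosen as the smallest scales at which the frontier
  dynamics — multi-level frontiers, duplicate collisions, non-trivial
  component structure — are all exercised; the kernels are plain
  vectorized R and handle the generators' desk-scale defaults
  (n ≤ 5,000) comfortably.

## Known limitations

* The kernels are single-threaded R; they implement frontier *semantics*,
  not a parallel runtime, and are not intended for organism-scale
  networks with millions of edges.
* No direction-optimizing BFS, Δ-stepping, or incremental component
  maintenance.
* Coexpression edges are plain Pearson thresholding — no shrinkage,
  partial correlation, or multiple-testing control; those belong to
  dedicated coexpression packages.
* Missing expression values are handled by dropping the gene, never by
  imputation or pairwise-complete correlations.
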