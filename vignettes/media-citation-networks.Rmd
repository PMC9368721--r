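---
title: "Analysing global media citation networks with citenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing global media citation networks with citenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a public-health emergency breaks, news about it does not flow through
independent channels: media outlets cite one another, newswires feed
national papers, and a handful of agencies end up brokering most of the
international flow of risk information. `citenet` models this as a *media
citation network*: a simple directed graph whose nodes are media outlets,
whose edge direction follows the flow of information (the citing outlet
points at the cited one), and whose positive integer edge weights count
citations. The package provides the full analysis chain for such networks —
construction from citation records or raw snippets, global topology,
core–periphery structure, peripheral communities, and per-outlet
activity/influence scores — plus a synthetic media-system generator so the
whole chain can be exercised and validated without access to any
proprietary news corpus.

```{r}
library(citenet)
```

## Network construction

`build_network()` turns `(citing, cited, count)` records into a validated
network: duplicate ordered pairs are merged by summing counts,
self-citations are rejected (a citation is by definition between distinct
outlets), and outlets that neither cite nor are cited are excluded — only
participants in the citation flow are nodes. `extract_citations()`
optionally produces the records from raw report snippets using an outlet
thesaurus; matching is case-insensitive and longest-alias-first so that a
short name nested in a longer official name ("Post" inside "The Washington
Post") is not double counted, and each detected mention yields one record
(a report that names the same outlet twice contributes two citations — the
alternative, once per report, is not distinguishable from the data model
and we fix the convention here).

All topological statistics operate on `undirected_view()`: direction and
weights describe *who feeds whom* and *how much*, while questions of
reachability, clustering and cohesion are about the underlying contact
structure.

## Global topology

`overall_metrics()` reports node/edge counts, total weight, the directed
density $E/(N(N-1))$, and the weakly connected component structure.
Scale-freeness is assessed by `fit_power_law()` on the complementary
cumulative degree distribution $F(n)$ (the fraction of nodes with degree at
least $n$): the model is $F(n) = a\,n^{-b}$ and the fit is ordinary least
squares of $\log_{10} F$ on $\log_{10} n$, because the quantity of interest
is the regression slope of the empirical CCDF, not a maximum-likelihood
tail index. A useful identity when reading $b$: a pure
preferential-attachment network has degree exponent 3, hence a CCDF
exponent near 2.

`small_world_stats()` returns the characteristic path length (mean BFS
distance over unordered connected pairs, computed within the largest
component, since cross-component distances are undefined) and the average
local clustering coefficient over *all* nodes, with the convention that a
node of degree below 2 has coefficient 0. That convention matters: leaving
such nodes out would inflate the average on star-like media systems.

## Core and periphery

The core is identified structurally, not by degree ranking, because highly
cited outlets are not automatically effective propagators.
`k_shell_decomposition()` iteratively strips minimum-degree nodes: at
stage $k$ every node of current degree $\le k$ is removed (cascading) and
assigned shell index $k$, starting at $k = 1$. Pruning is by *degree* on
the undirected unweighted view; because citation data sometimes motivates
pruning by citation volume instead, a `weighted = TRUE` switch prunes by
citation strength, but the default follows the convention that topology
ignores weights.

The threshold between core and periphery comes from the *crust-component
crossover*. For each $k$, the $k$-crust (nodes with shell $\le k$) is
examined: `crust_component_profile()` records its largest and
second-largest component sizes. As $k$ grows, peripheral fragments first
accrete (second-largest grows), until at some $k^\*$ the crust's largest
component jumps sharply while the second-largest starts shrinking — the
deep shells at $k^\*$ and above are what holds the network together. The
published description of this rule is verbal, so
`select_core_threshold()` fixes a deterministic operationalisation:
$k^\*$ maximises $\Delta(k) = \mathrm{largest}(k) -
\mathrm{largest}(k-1)$ among those $k$ where the second-largest does not
grow, falling back to the unconstrained argmax when no $k$ qualifies, with
ties broken toward the smallest $k$. The core is the $k^\*$-core, the
periphery the $(k^\*-1)$-crust. `core_coverage()` measures the fraction of
outlets in or directly adjacent to the core, and `core_country_matrix()`
aggregates core-internal cross-border flows, ordered so the heaviest
country pairs sit in the upper-left corner.

## Peripheral communities

Communities in the periphery are found with the classic divisive
Girvan–Newman procedure: `edge_betweenness()` (Brandes accumulation over
BFS shortest-path DAGs, fractional credit across equal-length paths) is
recomputed after **every single** edge removal, and the edge with maximal
betweenness is removed, ties broken by lexicographic endpoint order so
repeated runs are identical. Each removal that disconnects a component
records a candidate partition, scored by the modularity
$Q = \sum_i (e_{ii} - a_i^2)$ on the original component ($e_{ii}$ the
fraction of its edges inside community $i$, $a_i$ the fraction of edge
endpoints in $i$). `best_partition()` returns the candidate with maximal
$Q$, preferring fewer communities on ties; the initial component partition
is itself a candidate, so an already-disconnected input resolves to its
components without any removal. $Q$ is evaluated unweighted, matching the
topology convention; a weighted variant is deliberately out of scope.

In `run_stage()` community detection is applied to every peripheral
component with at least `min_community_component` nodes (default 6 — below
that a "community structure" is not meaningful). When the selected core
swallows the entire network, as happens on small dense toys, the same
procedure is applied to the full graph's components instead, so the
community section of a report is never silently empty for a structured
input.

## Outlet scores

Activity is citation volume: a node's strength (weighted in-degree plus
weighted out-degree) normalised by $N - 1$ (`normalized_degree()`), which
makes scores comparable across stages with different network sizes. Note
the weighted reading is forced by the data: normalised scores above
$2$ are impossible for unweighted degrees yet occur in real media
networks. A node's *activity share* is its strength over twice the total
edge weight — every citation contributes one endpoint to each of the two
outlets involved, so shares sum to 1. The published per-outlet activity
percentages cannot be reconstructed exactly from recoverable inputs (their
normaliser is unstated); we therefore fix the endpoint-mass definition and
document it.

Influence is a PageRank variant (`pagerank()`). With probability $1 - d$
an editor accesses an original report directly; with probability $d$ they
follow the citation chain, distributing their attention over the outlets
they cite proportionally to citation weights:
$$PR(A) = \frac{1-d}{N} + d \sum_{T_i} \frac{n_{T_i \to A}}{C_{T_i}}
PR(T_i).$$
The damping factor is therefore not the web-surfing 0.85 but an
empirical quantity of the media system: the proportion of reports that
cite external sources, `estimate_damping_factor()` = citation connections
/ reports (about 0.13 in pandemic-period news corpora). Since total
PageRank is 1, influence shares are simply scores × 100
(`influence_share()`).

Numerical choices: iteration starts uniform; dangling outlets (no outgoing
citations) redistribute their $d \cdot PR$ uniformly, the convention that
preserves the sum-to-1 contract the rank-leak problem motivates; the
update is *lazy* (the new vector is averaged with the old), which leaves
the fixed point unchanged but keeps the iteration convergent even at
$d = 1$ on periodic structures; convergence is declared when the L1
residual of the true fixed-point map falls below `tolerance` (default
1e-9, cap 1000 iterations), so the returned vector satisfies the defining
equation to that accuracy regardless of the lazy stepping. Exceeding the
cap raises a convergence error carrying the last residual rather than
returning a silent approximation.

`compare_stages()` aligns two stages by outlet and country; entities
absent from a stage are reported as absent (`NA`), never as zero shares,
and core node/edge ratios quantify how the backbone grows between stages.

## The synthetic media system

`generate_citation_network()` produces networks with the statistical
signature of real media citation data, with planted ground truth for every
downstream stage:

* **Country structure** — country sizes follow a Zipf-like rank law with
  exponent `country_size_skew` (default 1.2, a typical skew for media
  markets: a few countries host most outlets). Codes are drawn from the
  real ISO 3166-1 alpha-2 pool so continent lookups work on synthetic data.
* **Heavy-tailed backbone** — preferential attachment with
  `attachment_edges` (default 2) citations per arriving outlet: new
  outlets cite established ones proportionally to connectivity, giving a
  CCDF exponent near 2.
* **Geographic affinity** — each backbone citation is rewired to a
  same-country outlet with probability `within_country_affinity` (default
  0.3), producing the domestic clustering real systems show.
* **Planted core** — the `planted_core_size` best-connected outlets are
  densified by adding edges among them until each has core-internal degree
  at least $\lceil 0.6 (S-1) \rceil$; this guarantees a deep shell that
  the crossover rule should find, while leaving the degree tail intact.
* **Planted communities** — blocks of given size with internal edge
  probability `p_in` and cross-block probability `p_out`, allocated
  country-affinely, emulating the peripheral cliques of geographically and
  culturally close outlets.
* **Corpus** — `generate_report_corpus()` publishes `n_reports` reports;
  each cites an external outlet with probability `citation_prob` (default
  0.13), so the corpus's ground-truth damping factor is known exactly.
* **Weights** — citation multiplicities are $1 + \mathrm{Geom}$ with mean
  `weight_mean` (default 3): positive integers with a controllable mean.

One config seed drives all draws, so identical configurations reproduce
bit-identical systems. What the generator does **not** emulate: report
text and language, publication timing, topic dynamics, media ownership
ties, and the retrieval/cleaning pipeline that produces a real corpus.
Passing tests on synthetic systems therefore validate the *algorithms*
(recovery of planted structure, agreement with independent oracles, exact
arithmetic on published counts), not the empirical claims about any
particular news corpus — the real corpora behind published media-network
studies are proprietary and are not redistributed here.

## Validation strategy and problem sizes

Every algorithm is checked against an independent oracle in the test
suite: edge betweenness against exhaustive shortest-path enumeration
(graphs up to 12 nodes, 100 seeds), k-shell against repeated
minimum-degree deletion (up to 50 nodes), PageRank against the exact
linear-system solution (up to 50 nodes, 100 seeds; $d \in \{0, 0.13,
0.85\}$, plus sum-to-1 at $d = 1$), path lengths against an all-pairs
distance matrix, and the power-law fit against synthetic exact power laws.
Recovery experiments use 300-outlet systems with a 20-outlet planted core
(20 seeds), 24-outlet three-block planted partitions (20 seeds), 2000-node
attachment backbones for the degree exponent (10 seeds), and
100,000-report corpora for damping recovery — sizes chosen so the full
suite runs in well under a minute per module while keeping sampling error
far below the tolerances asserted.

## Limitations

* Girvan–Newman recomputes betweenness after every removal, which is
  $O(E^2 V)$; it is intended for peripheral components (tens of nodes), as
  in the analysis it supports, not for whole large graphs. Faster
  optimisers (Louvain/Leiden) are deliberately out of scope because the
  recorded dendrogram and its deterministic tie-breaks are part of the
  method.
* The crossover rule requires at least two crust levels; a single-shell
  network returns its only $k$ flagged degenerate.
* The power-law fit is a descriptive regression, not a goodness-of-fit
  test; no Kolmogorov–Smirnov or likelihood-ratio machinery is provided.
* Alias matching is exact (case-insensitive substring); fuzzy matching and
  name disambiguation are out of scope.
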