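# citenet

Directed citation-network analysis of global news flow.

When media outlets report on a fast-moving public-health emergency they
cite one another, and the resulting *media citation network* — outlets as
nodes, edge direction following the flow of information, integer weights
counting citations — determines how quickly and through whom risk
information spreads. `citenet` is an R package for analysing such
networks end to end:

* **Construction** — from `(citing, cited, count)` records or from raw
  report snippets matched against an outlet thesaurus
  (longest-alias-first, case-insensitive); duplicate pairs merged,
  self-citations rejected, isolated outlets excluded.
* **Global topology** — node/edge/weight counts, directed density
  `E/(N(N−1))`, weak components; scale-freeness via an OLS fit of the
  complementary cumulative degree distribution `F(n) = a·n^(−b)` on
  log–log axes; small-world statistics (characteristic path length within
  the largest component, average local clustering).
* **Core–periphery** — k-shell decomposition by iterative degree pruning,
  and core selection by the *crust-component crossover*: the threshold k\*
  at which the k-crust's largest component jumps while its second-largest
  starts shrinking; the core is the k\*-core, plus core coverage and the
  core's cross-country citation matrix.
* **Peripheral communities** — classic Girvan–Newman (edge betweenness
  recomputed after every removal, deterministic tie-breaks) scored by
  modularity `Q = Σ(e_ii − a_i²)`.
* **Outlet scores** — activity as citation strength normalised by `N−1`;
  influence as a weighted PageRank
  `PR(A) = (1−d)/N + d·Σ n_{Ti→A}/C_{Ti}·PR(Ti)` whose damping factor is
  *estimated from the corpus* as the proportion of reports citing external
  sources (≈ 0.13 for pandemic-period news), not the web default 0.85;
  activity/influence shares and two-stage comparisons.
* **Synthetic media systems** — a generator with Zipf-skewed country
  sizes, a preferential-attachment backbone, country-affine rewiring, a
  planted dense core and planted community blocks, plus a report corpus
  with known ground-truth damping factor, so every stage is testable
  without a proprietary news corpus.

See `vignettes/media-citation-networks.Rmd` for the methods account.

## Worked example

```r
library(citenet)

cfg <- synthetic_config(
  n_outlets = 400, n_countries = 25, planted_core_size = 25,
  planted_communities = list(c(10, 0.8, 0.01), c(8, 0.8, 0.01)),
  n_reports = 50000, citation_prob = 0.13, seed = 2020)

gen    <- generate_citation_network(cfg)
corp   <- generate_report_corpus(cfg, gen$network)
report <- run_stage(gen$network, corpus = corp$summary,
                    stage_label = "alert-stage")
report
#> stage_report [alert-stage]
#>   nodes 400 | edges 1045 | weight 3117 | density 0.007 | components 1 | largest 400
#>   power law: F(n) = 3.470 n^-1.532 (r2 = 0.886)
#>   path length 3.557 | clustering 0.100
#>   shells: 15 | core: 3-core, 172 nodes, coverage 92%
#>   peripheral components partitioned: 4 (Q = 0.788, 0.414, 0.494, 0.398)
```

The summary reads: a 400-outlet system with 1045 citation links carrying
3117 citations (density 0.007 — sparse, like real media networks); the
degree tail follows a power law with CCDF exponent 1.53; any two outlets
are ~3.6 citation steps apart with non-trivial clustering (small world);
the crossover picks the 3-core (172 outlets) whose direct reach covers
92% of the system; and the four sizable peripheral components split into
communities with modularities 0.79/0.41/0.49/0.40.

```r
head(report$scores[, c("id", "country", "strength", "ndegree",
                       "pagerank", "influence_share")], 5)
#>      id country strength   ndegree    pagerank influence_share
#> 1 M0004      SD      124 0.3107769 0.005598787       0.5598787
#> 2 M0003      BO      115 0.2882206 0.004918878       0.4918878
#> 3 M0035      GM      114 0.2857143 0.005075231       0.5075231
#> 4 M0005      HU      111 0.2781955 0.005892121       0.5892121
#> 5 M0023      BO      107 0.2681704 0.005058868       0.5058868

report$damping$d                   # corpus-estimated damping factor
#> [1] 0.12788

planted <- gen$ground_truth$id[gen$ground_truth$core]
mean(planted %in% report$core$core_nodes)   # planted-core recovery
#> [1] 1
```

The most active outlet (id `M0004`, strength 124) has normalised degree
124/399 ≈ 0.31; its influence share is its PageRank as a percentage
(0.56% of network-wide influence). The corpus-estimated damping factor
recovers the generator's true 0.13 to within binomial error, and the
selected core contains every planted core outlet.

Two stages are compared with `run_comparison(run_stage(...),
run_stage(...))`, which aligns outlet and country shares and reports core
node/edge growth ratios. A thin command-line front end is installed at
`inst/cli/citenet.R` (`simulate`, `stage`, `compare` subcommands).

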