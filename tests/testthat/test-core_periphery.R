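test_that("k-shell assigns hand-computable shell indices", {
  expect_equal(unname(k_shell_decomposition(path3())$shell), c(1, 1, 1))

  sp <- k_shell_decomposition(triangle_pendant())
  expect_equal(sp$shell[["d"]], 1)          # pendant
  expect_equal(unname(sp$shell[c("a", "b", "c")]), c(2, 2, 2))

  k4 <- ugraph(letters[1:4], t(combn(4, 2)))
  expect_equal(unname(k_shell_decomposition(k4)$shell), rep(3, 4))
})

test_that("k-shell matches the minimum-degree-deletion oracle and invariants", {
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    g <- random_ugraph(sample(10:50, 1), runif(1, 0.05, 0.25), seed)
    sh <- k_shell_decomposition(g)
    expect_equal(sh$shell, oracle_k_shell(g))
    ## shell(v) <= degree(v)
    deg <- citenet:::ug_degree(g)
    expect_true(all(sh$shell <= pmax(deg, 1)))
    ## matches igraph coreness with the 1-based bottom shell
    ig <- igraph::graph_from_edgelist(citenet:::ug_edges(g), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, length(g$ids) - igraph::vcount(ig)))
    expect_equal(unname(sh$shell), pmax(igraph::coreness(ig), 1))
    ## nestedness: the (k+1)-core is inside the k-core
    for (k in seq_len(sh$k_max - 1)) {
      expect_true(all(names(sh$shell)[sh$shell >= k + 1] %in%
                        names(sh$shell)[sh$shell >= k]))
    }
  }
})

test_that("crust profile records component sizes per k", {
  ## two triangles attached by single edges to a 4-clique core
  ids <- letters[1:10]
  e <- rbind(c(1, 2), c(1, 3), c(2, 3),          # triangle 1 (shell 2)
             c(4, 5), c(4, 6), c(5, 6),          # triangle 2 (shell 2)
             c(7, 8), c(7, 9), c(7, 10), c(8, 9), c(8, 10), c(9, 10), # K4
             c(1, 7), c(4, 8))                   # attachments
  g <- ugraph(ids, e)
  sh <- k_shell_decomposition(g)
  prof <- crust_component_profile(g, sh)
  ## at k = 2 the two triangles are separate crust components
  expect_equal(prof$largest[prof$k == 2], 3)
  expect_equal(prof$second[prof$k == 2], 3)
  ## at k_max the crust is the whole graph
  expect_equal(prof$largest[prof$k == sh$k_max], 10)
  ## largest component size is non-decreasing in k
  expect_true(all(diff(prof$largest) >= 0))
})

test_that("edgeless crusts consist of singleton components", {
  star <- ugraph(letters[1:5], cbind(1, 2:5))
  sh <- k_shell_decomposition(star)
  expect_equal(sh$k_max, 1)
  prof <- crust_component_profile(star, sh)
  expect_equal(prof$largest, 5)
})

test_that("crossover rule selects the constrained largest jump", {
  prof <- data.frame(k = 1:5, largest = c(5, 6, 7, 30, 32),
                     second = c(4, 5, 6, 3, 2))
  expect_equal(select_core_threshold(prof)$k_star, 4)

  ## strictly linear growth, constant second-largest: smallest argmax
  prof2 <- data.frame(k = 1:4, largest = c(2, 4, 6, 8), second = rep(1, 4))
  expect_equal(select_core_threshold(prof2)$k_star, 2)

  one <- data.frame(k = 3, largest = 10, second = 2)
  sel <- select_core_threshold(one)
  expect_true(sel$degenerate)
  expect_equal(sel$k_star, 3)

  ## when the second-largest never shrinks, fall back to the global argmax
  prof3 <- data.frame(k = 1:3, largest = c(1, 2, 9), second = c(0, 1, 2))
  expect_equal(select_core_threshold(prof3)$k_star, 3)
})

test_that("core coverage counts the core and its direct neighbours", {
  net <- toy_network()
  expect_equal(core_coverage(net, net$nodes$id), 1)

  ## star: the centre alone covers everything
  outlets <- media_outlets(letters[1:6], country = rep("US", 6))
  star <- build_network(
    data.frame(citing = letters[2:6], cited = "a", count = 1L), outlets)
  expect_equal(core_coverage(star, "a"), 1)
  expect_equal(core_coverage(star, character(0)), 0)

  ## 10-node network, 2-node core touching 6 others -> 0.8
  outlets <- media_outlets(letters[1:10], country = rep("US", 10))
  recs <- data.frame(
    citing = c("a", "a", "a", "b", "b", "b", "i", "a"),
    cited = c("c", "d", "e", "f", "g", "h", "j", "b"),
    count = 1L)
  net10 <- build_network(recs, outlets)
  expect_equal(core_coverage(net10, c("a", "b")), 0.8)
})

test_that("core country matrix keeps only cross-country core flows", {
  net <- toy_network()
  mat <- core_country_matrix(net, net$nodes$id)
  expect_true(all(diag(mat) == 0))
  ## total = total cross-country core weight (toy has no domestic edges)
  expect_equal(sum(mat), sum(net$edges$weight))
  ## ordered by descending total citations
  tot <- rowSums(mat) + colSums(mat)
  expect_true(all(diff(tot) <= 0))

  ## single-country core: all-zero matrix
  outlets <- media_outlets(c("A", "B"), country = c("US", "US"))
  dom <- build_network(
    data.frame(citing = "A", cited = "B", count = 3L), outlets)
  expect_true(all(core_country_matrix(dom, c("A", "B")) == 0))
})

test_that("weighted pruning mode uses citation strength", {
  outlets <- media_outlets(letters[1:4], country = rep("US", 4))
  ## star with heavy weights: weighted shells exceed unweighted ones
  recs <- data.frame(citing = c("a", "a", "a"), cited = c("b", "c", "d"),
                     count = 5L)
  net <- build_network(recs, outlets)
  unw <- k_shell_decomposition(undirected_view(net))
  wtd <- k_shell_decomposition(net, weighted = TRUE)
  expect_equal(unw$k_max, 1)
  expect_equal(wtd$shell[["b"]], 5)
})

test_that("the crossover core recovers a planted dense core", {
  hits <- numeric(0)
  for (seed in 1:5) {
    cfg <- synthetic_config(n_outlets = 300, n_countries = 20,
                            planted_core_size = 20, seed = seed)
    gen <- generate_citation_network(cfg)
    core <- core_assignment(gen$network)$core_nodes
    planted <- gen$ground_truth$id[gen$ground_truth$core]
    hits <- c(hits, mean(planted %in% core))
  }
  expect_gte(mean(hits), 0.8)
})
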