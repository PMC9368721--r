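## a 414-node network in which one outlet has citation strength 672:
## its normalised degree must print as 1.627119 at 6 decimals
test_that("normalised degree divides strength by N - 1", {
  n <- 414
  ids <- sprintf("o%03d", 1:n)
  outlets <- media_outlets(ids, country = rep("US", n))
  recs <- rbind(
    data.frame(citing = ids[1], cited = ids[2], count = 672L),
    data.frame(citing = ids[2:(n - 1)], cited = ids[3:n], count = 1L))
  net <- build_network(recs, outlets)
  nd <- normalized_degree(net)
  expect_equal(round_report(nd[[ids[1]]], 6), 1.627119)
  expect_equal(nd[[ids[1]]], 672 / 413)

  expect_error(normalized_degree(build_network(recs[0, ], outlets)),
               class = "citenet_input_error")
})

test_that("damping factor is the proportion of citing reports", {
  est <- estimate_damping_factor(32556, 246759)
  expect_equal(round_report(est$d, 2), 0.13)
  expect_equal(estimate_damping_factor(130, 1000)$d, 0.13)
  expect_equal(estimate_damping_factor(0, 500)$d, 0)
  expect_error(estimate_damping_factor(10, 0),
               class = "citenet_input_error")
  expect_warning(clamped <- estimate_damping_factor(15, 10), "clamped")
  expect_equal(clamped$d, 1)
})

test_that("PageRank limits behave as the model predicts", {
  net <- toy_network()
  n <- nrow(net$nodes)
  expect_equal(unname(pagerank(net, d = 0)), rep(1 / n, n))

  ## two mutually citing nodes: symmetry forces 0.5 each
  outlets <- media_outlets(c("A", "B"), country = c("US", "CN"))
  pair <- build_network(
    data.frame(citing = c("A", "B"), cited = c("B", "A"), count = c(3L, 8L)),
    outlets)
  for (d in c(0, 0.13, 0.85, 1)) {
    pr <- pagerank(pair, d = d)
    expect_equal(unname(pr), c(0.5, 0.5))
  }

  ## A cites B and C with equal weight: matches the exact linear solution
  outlets <- media_outlets(c("A", "B", "C"), country = rep("US", 3))
  fork <- build_network(
    data.frame(citing = c("A", "A"), cited = c("B", "C"), count = 2L),
    outlets)
  pr <- pagerank(fork, d = 0.13)
  expect_equal(pr, oracle_pagerank(fork, 0.13), tolerance = 1e-9)
})

test_that("PageRank equals the linear-system oracle and sums to one", {
  for (seed in 1:20) {
    net <- random_network(sample(5:50, 1), runif(1, 0.02, 0.2), seed)
    for (d in c(0, 0.13, 0.85, 1)) {
      pr <- pagerank(net, d = d)
      expect_equal(sum(pr), 1, tolerance = 1e-9)
      if (d < 1) {
        expect_equal(pr, oracle_pagerank(net, d), tolerance = 1e-8)
      }
    }
  }
})

test_that("increasing d widens the PageRank spread", {
  outlets <- media_outlets(c("A", "B", "C"), country = rep("US", 3))
  net <- build_network(
    data.frame(citing = c("A", "B", "A"), cited = c("B", "C", "C"),
               count = c(1L, 1L, 2L)),
    outlets)
  spread <- vapply(c(0, 0.13, 0.5, 0.85), function(d) {
    pr <- pagerank(net, d = d)
    max(pr) - min(pr)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("share tables map PageRank to influence percentages", {
  expect_equal(influence_share(0.011430), 1.143)
  expect_equal(round_report(influence_share(0.004814), 3), 0.481)

  net <- toy_network()
  sc <- node_shares(net)
  expect_equal(sum(sc$activity_share), 1, tolerance = 1e-9)
  expect_equal(sum(sc$influence_share), 100, tolerance = 1e-6)
  expect_true(all(sc$ndegree >= 0 & sc$pagerank >= 0))

  ## uniform weights -> equal activity shares
  outlets <- media_outlets(c("A", "B", "C", "D"), country = rep("US", 4))
  ring <- build_network(
    data.frame(citing = c("A", "B", "C", "D"),
               cited = c("B", "C", "D", "A"), count = 1L),
    outlets)
  rs <- node_shares(ring)
  expect_equal(length(unique(round(rs$activity_share, 12))), 1)
})

test_that("stage comparison reports share changes and size ratios", {
  net <- toy_network()
  sc <- node_shares(net)
  cmp <- compare_stages(sc, sc, net, net,
                        core1 = net$nodes$id, core2 = net$nodes$id)
  expect_true(all(cmp$outlets$change == 0))
  expect_true(all(cmp$countries$change == 0))
  expect_equal(cmp$ratios$node_ratio, 1)
  expect_equal(cmp$ratios$core_edge_ratio, 1)

  ## cores of 43 vs 192 nodes and 304 vs 2699 edges give the printed ratios
  expect_equal(round_report(192 / 43, 2), 4.47)
  expect_equal(round_report(2699 / 304, 2), 8.88)

  ## entities absent from a stage are NA, not zero
  half <- node_shares(build_network(
    data.frame(citing = "AP", cited = "XH", count = 2L),
    media_outlets(c("AP", "XH"), country = c("US", "CN"))))
  cmp2 <- compare_stages(half, sc, net, net)
  expect_true(anyNA(cmp2$outlets$stage1))
  expect_false(anyNA(cmp2$outlets$stage2))
})
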