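make_thesaurus <- function() {
  data.frame(
    id = c("XH", "WP", "WP", "A"),
    alias = c("Xinhua News Agency", "The Washington Post", "Post",
              "Outlet A"),
    stringsAsFactors = FALSE)
}

test_that("citation extraction matches thesaurus names in snippets", {
  th <- make_thesaurus()
  reports <- data.frame(
    report_id = 1,
    outlet_id = "A",
    text = "according to Xinhua News Agency, cases rose")
  res <- extract_citations(reports, th)
  expect_equal(res$records,
               data.frame(citing = "A", cited = "XH", count = 1L))

  ## no thesaurus name in the snippet -> empty
  none <- extract_citations(
    data.frame(report_id = 1, outlet_id = "A", text = "no sources here"), th)
  expect_equal(nrow(none$records), 0)

  ## an outlet quoting itself by name produces no record
  self <- extract_citations(
    data.frame(report_id = 1, outlet_id = "XH",
               text = "Xinhua News Agency reported from Wuhan"), th)
  expect_equal(nrow(self$records), 0)
})

test_that("matching is case-insensitive and longest-alias-first", {
  th <- make_thesaurus()
  reports <- data.frame(
    report_id = 1, outlet_id = "A",
    text = "THE WASHINGTON POST and the post said so")
  res <- extract_citations(reports, th)
  ## "Post" inside "The Washington Post" must not double count; the free-
  ## standing "post" still matches the short alias
  expect_equal(res$records$cited, c("WP", "WP"))
  expect_equal(nrow(res$records), 2)
})

test_that("reports from unknown publishers are skipped with a warning", {
  th <- make_thesaurus()
  reports <- data.frame(
    report_id = 1:2, outlet_id = c("ZZ", "A"),
    text = c("Xinhua News Agency", "Xinhua News Agency"))
  expect_warning(res <- extract_citations(reports, th), "skipped")
  expect_equal(res$n_skipped_reports, 1)
  expect_equal(res$records$citing, "A")
})

test_that("extraction output is invariant to report order", {
  th <- make_thesaurus()
  reports <- data.frame(
    report_id = 1:3, outlet_id = c("A", "XH", "A"),
    text = c("per The Washington Post", "the Post said", "Xinhua News Agency"))
  res1 <- extract_citations(reports, th)
  res2 <- extract_citations(reports[c(3, 1, 2), ], th)
  expect_equal(res1$records, res2$records)
})

test_that("network construction merges duplicates and drops isolates", {
  outlets <- media_outlets(LETTERS[1:5], country = rep("US", 5))
  records <- data.frame(citing = c("A", "A"), cited = c("B", "B"),
                        count = c(2L, 3L))
  net <- build_network(records, outlets)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 5)

  empty <- build_network(records[0, ], outlets)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)

  ## 3 records among 3 outlets + 2 unreferenced outlets -> 3 nodes
  records <- data.frame(citing = c("A", "B", "C"), cited = c("B", "C", "A"),
                        count = 1L)
  net <- build_network(records, outlets)
  expect_setequal(net$nodes$id, c("A", "B", "C"))
})

test_that("invalid records are rejected", {
  outlets <- media_outlets(c("A", "B"), country = c("US", "CN"))
  expect_error(
    build_network(data.frame(citing = "A", cited = "Z", count = 1L), outlets),
    "Z", class = "citenet_input_error")
  expect_error(
    build_network(data.frame(citing = "A", cited = "A", count = 1L), outlets),
    class = "citenet_input_error")
  expect_error(
    build_network(data.frame(citing = "A", cited = "B", count = 0L), outlets),
    class = "citenet_input_error")
  expect_error(media_outlets(c("A", "B"), country = c("USA", "CN")),
               class = "citenet_input_error")
})

test_that("country aggregation conserves total edge weight", {
  net <- toy_network()
  mat <- aggregate_by_country(net)
  expect_equal(sum(mat), sum(net$edges$weight))
  expect_equal(mat["US", "CN"], 4)
  expect_equal(mat["CN", "US"], 2)

  ## single-country network: one nonzero diagonal cell
  outlets <- media_outlets(c("A", "B"), country = c("US", "US"))
  net1 <- build_network(
    data.frame(citing = "A", cited = "B", count = 7L), outlets)
  mat1 <- aggregate_by_country(net1)
  expect_equal(mat1["US", "US"], 7)
  expect_equal(sum(mat1 != 0), 1)
})

test_that("networks round-trip through edge/node tables and GraphML", {
  net <- toy_network()
  ed <- tempfile(fileext = ".csv")
  nd <- tempfile(fileext = ".csv")
  write_edge_table(net, ed)
  write_node_table(net, nd)
  back <- read_network(ed, nd, stage_label = "toy")
  expect_equal(back, net)

  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back2 <- read_graphml(gml)
  expect_equal(back2$edges, net$edges)
  expect_equal(back2$nodes, net$nodes)
})
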