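## internal: citation strength = weighted in-degree + weighted out-degree
node_strength <- function(network) {
  ids <- network$nodes$id
  s <- setNames(numeric(length(ids)), ids)
  if (nrow(network$edges)) {
    out_w <- tapply(network$edges$weight, network$edges$from, sum)
    in_w <- tapply(network$edges$weight, network$edges$to, sum)
    s[names(out_w)] <- s[names(out_w)] + out_w
    s[names(in_w)] <- s[names(in_w)] + in_w
  }
  s
}

#' Normalised weighted degree
#'
#' A node's activity level: its citation strength (weighted in-degree plus
#' weighted out-degree, i.e. total citations sent and received) divided by
#' N - 1, which makes the measure comparable across networks of different
#' sizes.
#'
#' @param network A `citation_network` with at least 2 nodes.
#' @return Named numeric vector, node id -> ndegree.
#' @export
normalized_degree <- function(network) {
  stopifnot(inherits(network, "citation_network"))
  n <- nrow(network$nodes)
  if (n < 2L) {
    cn_stop("normalised degree requires at least 2 nodes",
            "citenet_input_error")
  }
  node_strength(network) / (n - 1)
}

#' Estimate the damping factor from a report corpus
#'
#' In a media system the damping factor d of the citation PageRank is the
#' probability that an editor reaches a story by following a citation chain
#' rather than accessing the original report, estimated as the proportion of
#' all reports that cite external sources: d = citation connections /
#' reports. Ratios above 1 (possible if reports carry multiple citations)
#' are clamped to 1 with a warning.
#'
#' @param n_citation_connections Number of citation connections, or a
#'   corpus-summary list with fields `n_citation_connections` and
#'   `n_reports`.
#' @param n_reports Total number of reports (> 0).
#' @return A list with `d`, `numerator`, `denominator`.
#' @export
#' @examples
#' estimate_damping_factor(32556, 246759)$d  # about 0.13
estimate_damping_factor <- function(n_citation_connections, n_reports) {
  if (is.list(n_citation_connections)) {
    s <- n_citation_connections
    n_reports <- s$n_reports
    n_citation_connections <- s$n_citation_connections
  }
  if (is.null(n_reports) || n_reports <= 0) {
    cn_stop("cannot estimate d from zero reports", "citenet_input_error")
  }
  d <- n_citation_connections / n_reports
  if (d > 1) {
    warning("citation connections exceed reports; damping factor clamped to 1")
    d <- 1
  }
  list(d = d, numerator = n_citation_connections, denominator = n_reports)
}

#' Citation-weighted PageRank with an empirical damping factor
#'
#' Power iteration of PR(A) = (1 - d)/N + d * sum_i w(Ti -> A)/C(Ti) * PR(Ti),
#' where C(Ti) is the total outgoing citation weight of Ti. Every node
#' receives the uniform (1 - d)/N share; each node passes on d times its
#' current score proportionally to its outgoing citation weights. Dangling
#' nodes (no outgoing citations) redistribute their d * PR share uniformly
#' over all nodes, which preserves the sum-to-1 property for every d in
#' [0, 1]. Iteration starts from the uniform vector; a lazy update
#' (averaging the current vector with its image) keeps the iteration
#' convergent even at d = 1 on periodic citation structures, and the
#' stopping rule is the L1 residual of the true fixed-point map dropping
#' below `tolerance`, so the returned vector satisfies the defining
#' equation to that accuracy regardless of the lazy stepping.
#'
#' @param network A `citation_network` with at least 1 node.
#' @param d Damping factor in [0, 1].
#' @param tolerance L1 convergence threshold.
#' @param max_iterations Iteration cap; exceeding it raises a convergence
#'   error carrying the last residual.
#' @return Named numeric vector of PageRank scores summing to 1.
#' @export
pagerank <- function(network, d = 0.13, tolerance = 1e-9,
                     max_iterations = 1000L) {
  stopifnot(inherits(network, "citation_network"))
  if (d < 0 || d > 1) cn_stop("d must lie in [0, 1]", "citenet_input_error")
  ids <- network$nodes$id
  n <- length(ids)
  if (!n) cn_stop("network has no nodes", "citenet_input_error")
  fi <- match(network$edges$from, ids)
  ti <- match(network$edges$to, ids)
  w <- network$edges$weight
  out_w <- numeric(n)
  if (length(fi)) {
    ow <- tapply(w, fi, sum)
    out_w[as.integer(names(ow))] <- ow
  }
  dangling <- out_w == 0
  frac <- if (length(w)) w / out_w[fi] else numeric(0)

  pr <- rep(1 / n, n)
  for (it in seq_len(max_iterations)) {
    inflow <- numeric(n)
    if (length(ti)) {
      contrib <- tapply(pr[fi] * frac, ti, sum)
      inflow[as.integer(names(contrib))] <- contrib
    }
    image <- (1 - d) / n + d * inflow + d * sum(pr[dangling]) / n
    res <- sum(abs(image - pr))
    if (res < tolerance) {
      return(setNames(image, ids))
    }
    pr <- (pr + image) / 2
  }
  cn_stop(sprintf("PageRank did not converge in %d iterations (L1 residual %g)",
                  max_iterations, res),
          "citenet_convergence_error")
}

#' Influence share from a PageRank score
#'
#' Because network-wide PageRank sums to 1, a node's share of total
#' influence is simply its PageRank expressed as a percentage.
#'
#' @param pr PageRank value(s).
#' @return Percentage value(s).
#' @export
#' @examples
#' influence_share(0.011430)  # 1.143
influence_share <- function(pr) pr * 100

#' Per-node score table
#'
#' Combines strength, normalised degree, PageRank and the two network-share
#' measures: activity share = strength / (2 x total edge weight) (each
#' citation contributes one endpoint to each of its two outlets), and
#' influence share = PageRank x 100.
#'
#' @param network A `citation_network` with positive total weight.
#' @param pagerank Named PageRank vector for the same network (computed with
#'   [pagerank()] if omitted).
#' @param d Damping factor forwarded to [pagerank()] when scores are not
#'   supplied.
#' @return `data.frame` with columns `id`, `country`, `strength`, `ndegree`,
#'   `pagerank`, `activity_share`, `influence_share`, sorted by decreasing
#'   ndegree.
#' @export
node_shares <- function(network, pagerank = NULL, d = 0.13) {
  stopifnot(inherits(network, "citation_network"))
  total_w <- sum(network$edges$weight)
  if (total_w <= 0) {
    cn_stop("activity shares are undefined for zero total weight",
            "citenet_input_error")
  }
  if (is.null(pagerank)) pagerank <- pagerank(network, d = d)
  s <- node_strength(network)
  nd <- normalized_degree(network)
  out <- data.frame(id = network$nodes$id,
                    country = network$nodes$country,
                    strength = unname(s[network$nodes$id]),
                    ndegree = unname(nd[network$nodes$id]),
                    pagerank = unname(pagerank[network$nodes$id]),
                    stringsAsFactors = FALSE)
  out$activity_share <- out$strength / (2 * total_w)
  out$influence_share <- influence_share(out$pagerank)
  out <- out[order(-out$ndegree, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare node scores and cores across two observation stages
#'
#' Aligns two score tables by outlet and by country, reporting each entity's
#' activity and influence share at both stages and their change; entities
#' absent from a stage carry `NA` (absent, not zero). Network-pair and
#' core-pair size ratios (stage 2 over stage 1) are included.
#'
#' @param scores1,scores2 Score tables from [node_shares()].
#' @param net1,net2 The corresponding networks.
#' @param core1,core2 Optional core node-id vectors; when given, core
#'   node/edge ratios are computed on the induced core subgraphs.
#' @return A list with `outlets`, `countries` (data frames) and `ratios`.
#' @export
compare_stages <- function(scores1, scores2, net1, net2,
                           core1 = NULL, core2 = NULL) {
  align <- function(k1, v1, k2, v2) {
    keys <- union(k1, k2)
    data.frame(entity = keys,
               stage1 = v1[match(keys, k1)],
               stage2 = v2[match(keys, k2)],
               change = v2[match(keys, k2)] - v1[match(keys, k1)],
               stringsAsFactors = FALSE)
  }
  outlets <- cbind(
    align(scores1$id, scores1$activity_share,
          scores2$id, scores2$activity_share),
    influence1 = scores1$influence_share[match(
      union(scores1$id, scores2$id), scores1$id)],
    influence2 = scores2$influence_share[match(
      union(scores1$id, scores2$id), scores2$id)])
  country_share <- function(sc) {
    tapply(sc$activity_share, sc$country, sum)
  }
  cs1 <- country_share(scores1)
  cs2 <- country_share(scores2)
  countries <- align(names(cs1), as.numeric(cs1), names(cs2), as.numeric(cs2))

  core_edges <- function(net, core) {
    sum(net$edges$from %in% core & net$edges$to %in% core)
  }
  ratios <- list(node_ratio = nrow(net2$nodes) / nrow(net1$nodes),
                 edge_ratio = nrow(net2$edges) / nrow(net1$edges))
  if (!is.null(core1) && !is.null(core2)) {
    ratios$core_node_ratio <- length(core2) / length(core1)
    ratios$core_edge_ratio <- core_edges(net2, core2) / core_edges(net1, core1)
  }
  list(outlets = outlets, countries = countries, ratios = ratios)
}
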