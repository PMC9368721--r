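#' Edge betweenness centrality
#'
#' For every edge, the number of shortest paths between unordered node pairs
#' that pass through it, with fractional credit split equally among
#' equal-length shortest paths (Brandes accumulation over breadth-first
#' shortest-path DAGs).
#'
#' @param graph A [ugraph()].
#' @return `data.frame` with columns `from`, `to` (node ids, `from < to`)
#'   and `betweenness`.
#' @export
edge_betweenness <- function(graph) {
  stopifnot(inherits(graph, "ugraph"))
  n <- ug_n(graph)
  if (!n) cn_stop("graph has no nodes", "citenet_input_error")
  e <- ug_edges(graph)
  if (!nrow(e)) {
    return(data.frame(from = character(), to = character(),
                      betweenness = numeric(), stringsAsFactors = FALSE))
  }
  key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  ekey <- key(e[, 1], e[, 2])
  bc <- numeric(nrow(e))

  for (s in seq_len(n)) {
    ## BFS from s recording sigma (path counts) and predecessors
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    preds <- rep(list(integer()), n)
    dist[s] <- 0L
    sigma[s] <- 1
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in graph$adj[[v]]) {
          if (dist[w] == -1L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    ## dependency accumulation in reverse BFS order
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        c_vw <- sigma[v] / sigma[w] * (1 + delta[w])
        bc[match(key(v, w), ekey)] <- bc[match(key(v, w), ekey)] + c_vw
        delta[v] <- delta[v] + c_vw
      }
    }
  }
  data.frame(from = graph$ids[e[, 1]], to = graph$ids[e[, 2]],
             betweenness = bc / 2, stringsAsFactors = FALSE)
}

#' Girvan-Newman divisive community detection
#'
#' Classic divisive procedure: recompute edge betweenness after every single
#' removal and delete the edge with the largest value (ties broken by
#' lexicographic order of the sorted endpoint-id pair). Whenever a removal
#' increases the number of connected components, the component partition is
#' recorded together with its modularity Q evaluated on the original graph.
#' The initial component partition is recorded as the dendrogram's starting
#' point, so a disconnected input already contributes a multi-community
#' candidate.
#'
#' @param graph A [ugraph()] with at least one edge.
#' @return A list of class `gn_dendrogram` with `initial` (list with
#'   `communities`, `q`) and `steps` (each: `edge`, `communities`, `q`).
#' @export
girvan_newman <- function(graph) {
  stopifnot(inherits(graph, "ugraph"))
  if (graph$m == 0L) {
    cn_stop("Girvan-Newman requires at least one edge", "citenet_input_error")
  }
  ids <- graph$ids
  comp_sets <- function(g) {
    comp <- ug_components(g)
    unname(split(g$ids, comp))
  }
  initial <- comp_sets(graph)
  dendro <- list(initial = list(communities = initial,
                                q = modularity(graph, initial)),
                 steps = list())
  work <- graph
  n_comm <- length(initial)
  while (work$m > 0L) {
    bc <- edge_betweenness(work)
    ## ties: lexicographic on (from, to); rows are already from < to by id index
    top <- which(bc$betweenness >= max(bc$betweenness) - 1e-12)
    top <- top[order(bc$from[top], bc$to[top])][1]
    keep <- !(seq_len(nrow(bc)) == top)
    e_idx <- cbind(match(bc$from[keep], work$ids), match(bc$to[keep], work$ids))
    work <- ugraph(work$ids, e_idx)
    comm <- comp_sets(work)
    if (length(comm) > n_comm) {
      n_comm <- length(comm)
      dendro$steps[[length(dendro$steps) + 1L]] <-
        list(edge = c(bc$from[top], bc$to[top]),
             communities = comm,
             q = modularity(graph, comm))
    }
  }
  class(dendro) <- "gn_dendrogram"
  dendro
}

#' Modularity Q of a partition
#'
#' Q = sum_i (e_ii - a_i^2), where e_ii is the fraction of edges with both
#' endpoints in community i and a_i the fraction of edge endpoints in
#' community i. Q is 0 for the single-community partition, approaches 1 for
#' a strong community structure and can be negative for a poor split.
#'
#' @param graph A [ugraph()] with at least one edge.
#' @param communities List of disjoint node-id vectors covering the graph.
#' @return Modularity value in [-1, 1).
#' @export
modularity <- function(graph, communities) {
  stopifnot(inherits(graph, "ugraph"))
  if (graph$m == 0L) {
    cn_stop("modularity is undefined on an edgeless graph",
            "citenet_input_error")
  }
  memb_ids <- unlist(communities, use.names = FALSE)
  if (anyDuplicated(memb_ids) || !setequal(memb_ids, graph$ids)) {
    cn_stop("communities must partition the node set", "citenet_input_error")
  }
  member <- integer(ug_n(graph))
  for (i in seq_along(communities)) {
    member[match(communities[[i]], graph$ids)] <- i
  }
  e <- ug_edges(graph)
  m <- nrow(e)
  same <- member[e[, 1]] == member[e[, 2]]
  e_ii <- tabulate(member[e[same, 1]], nbins = length(communities)) / m
  deg <- ug_degree(graph)
  a_i <- vapply(seq_along(communities),
                function(i) sum(deg[member == i]), numeric(1)) / (2 * m)
  sum(e_ii - a_i^2)
}

#' Best Girvan-Newman partition by modularity
#'
#' Runs [girvan_newman()] and returns the recorded partition (including the
#' initial component partition) with maximal Q; ties are broken toward the
#' fewest communities, then toward the earliest candidate, so repeated runs
#' agree exactly.
#'
#' @param graph A [ugraph()] with at least one edge.
#' @return A list with `communities` (list of node-id vectors) and `q`.
#' @export
best_partition <- function(graph) {
  dendro <- girvan_newman(graph)
  cands <- c(list(dendro$initial),
             lapply(dendro$steps, function(s) s[c("communities", "q")]))
  qs <- vapply(cands, function(cc) cc$q, numeric(1))
  sizes <- vapply(cands, function(cc) length(cc$communities), integer(1))
  best <- order(-qs, sizes, seq_along(cands))[1]
  cands[[best]]
}
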