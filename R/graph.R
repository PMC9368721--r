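## Lightweight undirected simple graph used by the topology, core-periphery
## and community modules. Nodes are indexed 1..n with character ids; the
## adjacency is a list of sorted integer neighbour vectors. All structural
## algorithms in the package (BFS, components, k-shell, betweenness) operate
## on this representation.

#' Construct an undirected simple graph
#'
#' @param ids Character vector of node identifiers (unique).
#' @param edges Two-column integer matrix of node indices (one row per
#'   undirected edge). Self-loops and duplicate pairs are dropped.
#' @return An object of class `ugraph` with elements `ids`, `adj`
#'   (neighbour index lists) and `m` (number of edges).
#' @export
ugraph <- function(ids, edges = matrix(integer(), ncol = 2)) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) cn_stop("node ids must be unique", "citenet_input_error")
  n <- length(ids)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n)) {
      cn_stop("edge endpoint out of range", "citenet_input_error")
    }
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]      # no loops
    edges <- cbind(pmin(edges[, 1], edges[, 2]),
                   pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
  }
  adj <- rep(list(integer()), n)
  if (nrow(edges)) {
    half <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    for (k in names(half)) adj[[as.integer(k)]] <- sort(half[[k]])
  }
  structure(list(ids = ids, adj = adj, m = nrow(edges)),
            class = "ugraph")
}

#' @export
print.ugraph <- function(x, ...) {
  cat(sprintf("ugraph: %d nodes, %d edges\n", length(x$ids), x$m))
  invisible(x)
}

## internal: n-of-nodes helper
ug_n <- function(g) length(g$ids)

## internal: integer degree vector
ug_degree <- function(g) vapply(g$adj, length, integer(1))

## internal: edge matrix (from < to, node indices)
ug_edges <- function(g) {
  n <- ug_n(g)
  from <- rep.int(seq_len(n), vapply(g$adj, length, integer(1)))
  to <- unlist(g$adj, use.names = FALSE)
  keep <- from < to
  cbind(from[keep], to[keep])
}

## internal: connected components by BFS; returns integer membership vector
ug_components <- function(g) {
  n <- ug_n(g)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- g$adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

## internal: BFS distances from source (index); unreachable = NA
ug_bfs <- function(g, s) {
  n <- ug_n(g)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  frontier <- s
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(g$adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

## internal: induced subgraph on node indices `keep`; preserves original ids
ug_induced <- function(g, keep) {
  keep <- sort(unique(as.integer(keep)))
  idx <- integer(ug_n(g))
  idx[keep] <- seq_along(keep)
  e <- ug_edges(g)
  if (nrow(e)) {
    sel <- idx[e[, 1]] > 0L & idx[e[, 2]] > 0L
    e <- cbind(idx[e[sel, 1]], idx[e[sel, 2]])
  }
  ugraph(g$ids[keep], e)
}
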