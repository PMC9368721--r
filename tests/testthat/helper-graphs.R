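## Toy graphs and independent brute-force oracles used across the suite.

## two triangles {a,b,c} and {d,e,f} joined by the bridge c-d
two_triangles_bridge <- function() {
  ids <- letters[1:6]
  ugraph(ids, rbind(c(1, 2), c(1, 3), c(2, 3),
                    c(4, 5), c(4, 6), c(5, 6),
                    c(3, 4)))
}

two_disjoint_triangles <- function() {
  ugraph(letters[1:6], rbind(c(1, 2), c(1, 3), c(2, 3),
                             c(4, 5), c(4, 6), c(5, 6)))
}

path3 <- function() ugraph(c("a", "b", "c"), rbind(c(1, 2), c(2, 3)))

triangle_pendant <- function() {
  ugraph(letters[1:4], rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4)))
}

## Erdos-Renyi undirected graph under a fixed seed
random_ugraph <- function(n, p, seed) {
  set.seed(seed)
  prs <- t(combn(n, 2))
  keep <- runif(nrow(prs)) < p
  ugraph(sprintf("v%02d", 1:n), prs[keep, , drop = FALSE])
}

## random directed weighted citation network (no self loops)
random_network <- function(n, p, seed, max_w = 5) {
  set.seed(seed)
  grid <- expand.grid(from = 1:n, to = 1:n)
  grid <- grid[grid$from != grid$to, ]
  keep <- grid[runif(nrow(grid)) < p, , drop = FALSE]
  ids <- sprintf("v%02d", 1:n)
  outlets <- media_outlets(ids, country = rep("US", n))
  if (!nrow(keep)) {
    keep <- data.frame(from = 1, to = 2)   # guarantee at least one edge
  }
  records <- data.frame(citing = ids[keep$from], cited = ids[keep$to],
                        count = sample.int(max_w, nrow(keep), replace = TRUE))
  build_network(records, outlets)
}

## oracle: edge betweenness by exhaustive shortest-path enumeration
oracle_edge_betweenness <- function(g) {
  n <- length(g$ids)
  e <- citenet:::ug_edges(g)
  key <- paste(e[, 1], e[, 2])
  bc <- setNames(numeric(nrow(e)), key)
  all_shortest_paths <- function(s, t) {
    ## BFS distances from s, then backtrack every shortest path from t
    dist <- citenet:::ug_bfs(g, s)
    if (is.na(dist[t])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) {
        paths[[length(paths) + 1L]] <<- rev(c(acc, v))
        return(invisible())
      }
      for (u in g$adj[[v]]) {
        if (!is.na(dist[u]) && dist[u] == dist[v] - 1L) walk(u, c(acc, v))
      }
    }
    walk(t, integer(0))
    paths
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_shortest_paths(s, t)
      if (!length(paths)) next
      credit <- 1 / length(paths)
      for (p in paths) {
        for (i in seq_len(length(p) - 1L)) {
          k <- paste(min(p[i], p[i + 1]), max(p[i], p[i + 1]))
          bc[k] <- bc[k] + credit
        }
      }
    }
  }
  data.frame(from = g$ids[e[, 1]], to = g$ids[e[, 2]],
             betweenness = unname(bc), stringsAsFactors = FALSE)
}

## oracle: shell indices by repeated deletion of a minimum-degree node
oracle_k_shell <- function(g) {
  n <- length(g$ids)
  active <- rep(TRUE, n)
  deg <- citenet:::ug_degree(g)
  shell <- integer(n)
  k <- 1L
  while (any(active)) {
    dmin <- min(deg[active])
    k <- max(k, dmin)
    v <- which(active & deg == dmin)[1]
    shell[v] <- k
    active[v] <- FALSE
    nb <- g$adj[[v]]
    deg[nb[active[nb]]] <- deg[nb[active[nb]]] - 1L
  }
  setNames(shell, g$ids)
}

## oracle: PageRank as the exact solution of its linear fixed point,
## dangling nodes redistributing uniformly
oracle_pagerank <- function(network, d) {
  ids <- network$nodes$id
  n <- length(ids)
  M <- matrix(0, n, n)        # M[i, j]: share of j's score flowing to i
  out_w <- setNames(numeric(n), ids)
  for (r in seq_len(nrow(network$edges))) {
    out_w[network$edges$from[r]] <- out_w[network$edges$from[r]] +
      network$edges$weight[r]
  }
  for (r in seq_len(nrow(network$edges))) {
    i <- match(network$edges$to[r], ids)
    j <- match(network$edges$from[r], ids)
    M[i, j] <- M[i, j] + network$edges$weight[r] / out_w[ids[j]]
  }
  dangling <- which(out_w == 0)
  M[, dangling] <- 1 / n
  pr <- solve(diag(n) - d * M, rep((1 - d) / n, n))
  setNames(pr, ids)
}

## a small two-country citation network used in ingest/metric tests
toy_network <- function() {
  outlets <- media_outlets(id = c("AP", "XH", "PA", "AFP"),
                           name = c("Associated Press", "Xinhua News Agency",
                                    "Press Association", "Agence France-Presse"),
                           country = c("US", "CN", "GB", "FR"))
  records <- data.frame(
    citing = c("AP", "AP", "XH", "PA", "AFP", "XH"),
    cited = c("XH", "PA", "AP", "AP", "XH", "PA"),
    count = c(4L, 1L, 2L, 3L, 1L, 2L))
  build_network(records, outlets, stage_label = "toy")
}
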