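#' Overall network metrics
#'
#' Summary statistics of a directed weighted citation network: node and edge
#' counts, total edge weight, directed density E / (N (N - 1)), the number
#' of weakly connected components and the size of the largest one.
#' Components are computed on the undirected view, since connectivity of the
#' information flow ignores edge direction. Density is returned at full
#' precision; round only when reporting (see [round_report()]).
#'
#' @param network A `citation_network`.
#' @return A list with `n_nodes`, `n_edges`, `total_weight`, `density`,
#'   `density_defined` (FALSE when N <= 1), `n_components`,
#'   `largest_component_size`.
#' @export
overall_metrics <- function(network) {
  stopifnot(inherits(network, "citation_network"))
  n <- nrow(network$nodes)
  e <- nrow(network$edges)
  g <- undirected_view(network)
  if (n > 0L) {
    comp <- ug_components(g)
    sizes <- tabulate(comp)
    ncomp <- length(sizes)
    largest <- max(sizes)
  } else {
    ncomp <- 0L
    largest <- 0L
  }
  list(n_nodes = n,
       n_edges = e,
       total_weight = sum(network$edges$weight),
       density = if (n > 1L) directed_density(n, e) else 0,
       density_defined = n > 1L,
       n_components = ncomp,
       largest_component_size = largest)
}

#' Directed graph density
#'
#' @param n_nodes Number of nodes N.
#' @param n_edges Number of directed edges E.
#' @return E / (N (N - 1)); 0 when N <= 1 (density undefined).
#' @export
#' @examples
#' directed_density(414, 1211)
directed_density <- function(n_nodes, n_edges) {
  if (n_nodes <= 1L) return(0)
  n_edges / (n_nodes * (n_nodes - 1))
}

#' Undirected unweighted view of a citation network
#'
#' Topological statistics (degree distribution, path lengths, clustering,
#' k-shell, communities) ignore direction and weights: the undirected edge
#' \{u, v\} is present iff u cites v or v cites u.
#'
#' @param network A `citation_network`.
#' @return A [ugraph()].
#' @export
undirected_view <- function(network) {
  stopifnot(inherits(network, "citation_network"))
  ids <- network$nodes$id
  e <- cbind(match(network$edges$from, ids), match(network$edges$to, ids))
  ugraph(ids, e)
}

#' Complementary cumulative degree distribution
#'
#' For every observed degree value n, F(n) is the fraction of nodes with
#' degree >= n. F is non-increasing and equals 1 at the minimum observed
#' degree.
#'
#' @param graph A [ugraph()] (non-empty).
#' @return `data.frame` with columns `degree` and `ccdf`.
#' @export
complementary_cumulative_distribution <- function(graph) {
  stopifnot(inherits(graph, "ugraph"))
  deg <- ug_degree(graph)
  if (!length(deg)) cn_stop("graph has no nodes", "citenet_input_error")
  vals <- sort(unique(deg))
  data.frame(degree = vals,
             ccdf = vapply(vals, function(k) mean(deg >= k), numeric(1)))
}

#' Fit a power law to a complementary cumulative degree distribution
#'
#' Ordinary least squares of log10 F on log10 n over the positive observed
#' degrees, following the scale-free regression model F(n) = a * n^-b. The
#' normalisation constant is a = 10^intercept and the power exponent is
#' b = -slope; `r_squared` is the coefficient of determination of the
#' log-log regression. Note the CCDF exponent of a scale-free network is one
#' less than its degree-distribution exponent (a degree exponent of 3 gives
#' b close to 2).
#'
#' @param dist `data.frame` as produced by
#'   [complementary_cumulative_distribution()].
#' @return A list with `a`, `b`, `r_squared` and `n_points`.
#' @export
fit_power_law <- function(dist) {
  stopifnot(is.data.frame(dist), all(c("degree", "ccdf") %in% names(dist)))
  pts <- dist[dist$degree > 0 & dist$ccdf > 0, , drop = FALSE]
  if (nrow(pts) < 3L) {
    cn_stop("power-law fit needs at least 3 distinct positive degree values",
            "citenet_degenerate_fit_error")
  }
  fit <- stats::lm(log10(ccdf) ~ log10(degree), data = pts)
  y <- log10(pts$ccdf)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(a = 10^unname(stats::coef(fit)[1]),
       b = -unname(stats::coef(fit)[2]),
       r_squared = r2,
       n_points = nrow(pts))
}

#' Small-world statistics
#'
#' Characteristic path length (mean breadth-first shortest-path distance
#' over all unordered connected node pairs within the largest component),
#' the average local clustering coefficient over all nodes of the full graph
#' (nodes of degree < 2 contribute 0), and the histogram of pairwise
#' distances within the largest component.
#'
#' @param graph A [ugraph()] (non-empty).
#' @return A list with `characteristic_path_length`,
#'   `average_local_clustering` and `path_length_histogram` (named integer
#'   vector, distance -> number of unordered pairs).
#' @export
small_world_stats <- function(graph) {
  stopifnot(inherits(graph, "ugraph"))
  n <- ug_n(graph)
  if (!n) cn_stop("graph has no nodes", "citenet_input_error")

  comp <- ug_components(graph)
  big <- which.max(tabulate(comp))
  members <- which(comp == big)
  sub <- ug_induced(graph, members)

  ## all-pairs BFS inside the largest component; each unordered pair counted
  ## once (source index < target index)
  hist <- integer(0)
  ns <- ug_n(sub)
  for (s in seq_len(ns)) {
    d <- ug_bfs(sub, s)
    d <- d[seq_len(ns) > s]
    d <- d[!is.na(d) & d > 0L]
    if (length(d)) {
      mx <- max(d)
      if (mx > length(hist)) hist <- c(hist, integer(mx - length(hist)))
      tab <- tabulate(d, nbins = mx)
      hist[seq_len(mx)] <- hist[seq_len(mx)] + tab
    }
  }
  names(hist) <- seq_along(hist)
  cpl <- if (sum(hist)) sum(as.integer(names(hist)) * hist) / sum(hist) else 0

  ## local clustering over the full graph
  cc <- vapply(seq_len(n), function(v) {
    nb <- graph$adj[[v]]
    k <- length(nb)
    if (k < 2L) return(0)
    links <- 0L
    for (i in seq_len(k - 1L)) {
      links <- links + sum(graph$adj[[nb[i]]] %in% nb[(i + 1L):k])
    }
    2 * links / (k * (k - 1))
  }, numeric(1))

  list(characteristic_path_length = cpl,
       average_local_clustering = mean(cc),
       path_length_histogram = hist)
}
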