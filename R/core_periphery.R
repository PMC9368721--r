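#' k-shell decomposition
#'
#' Iterative degree pruning on the undirected unweighted view: starting at
#' k = 1, all nodes of current degree <= k are repeatedly removed (together
#' with their edges) and assigned shell index k; when no such node remains,
#' k is incremented. Shell indices start at 1, so isolated and degree-1
#' nodes both land in the 1-shell. The result is independent of removal
#' order. With `weighted = TRUE` pruning uses the weighted degree (citation
#' strength) instead — an alternative reading of pruning "by edge weight" —
#' in which case a `citation_network` must be supplied.
#'
#' @param graph A [ugraph()], or a `citation_network` when
#'   `weighted = TRUE`.
#' @param weighted Prune by weighted degree instead of degree.
#' @return A list with `shell` (named integer vector, node id -> shell
#'   index) and `k_max`.
#' @export
k_shell_decomposition <- function(graph, weighted = FALSE) {
  if (weighted) {
    stopifnot(inherits(graph, "citation_network"))
    net <- graph
    graph <- undirected_view(net)
    ids <- graph$ids
    w <- matrix(0, ug_n(graph), ug_n(graph))
    fi <- match(net$edges$from, ids)
    ti <- match(net$edges$to, ids)
    for (i in seq_along(fi)) {
      w[fi[i], ti[i]] <- w[fi[i], ti[i]] + net$edges$weight[i]
      w[ti[i], fi[i]] <- w[ti[i], fi[i]] + net$edges$weight[i]
    }
    degfun <- function(active) rowSums(w[, active, drop = FALSE])
  } else {
    stopifnot(inherits(graph, "ugraph"))
  }
  n <- ug_n(graph)
  if (!n) cn_stop("graph has no nodes", "citenet_input_error")
  active <- rep(TRUE, n)
  deg <- if (weighted) degfun(active) else ug_degree(graph)
  shell <- integer(n)
  k <- 1L
  while (any(active)) {
    victims <- which(active & deg <= k)
    if (!length(victims)) {
      k <- k + 1L
      next
    }
    while (length(victims)) {
      shell[victims] <- k
      active[victims] <- FALSE
      if (weighted) {
        deg <- degfun(active)
      } else {
        for (v in victims) {
          nb <- graph$adj[[v]]
          nb <- nb[active[nb]]
          deg[nb] <- deg[nb] - 1L
        }
      }
      victims <- which(active & deg <= k)
    }
  }
  names(shell) <- graph$ids
  list(shell = shell, k_max = max(shell))
}

#' Crust component-size profile
#'
#' For each k in 1..k_max, the k-crust is the induced subgraph on nodes with
#' shell index <= k. The profile records the sizes of its largest and
#' second-largest connected components; the crossover where the largest
#' jumps while the second-largest starts shrinking marks the core threshold
#' (see [select_core_threshold()]).
#'
#' @param graph The [ugraph()] the decomposition was computed on.
#' @param shells Result of [k_shell_decomposition()].
#' @return `data.frame` with columns `k`, `largest`, `second`.
#' @export
crust_component_profile <- function(graph, shells) {
  stopifnot(inherits(graph, "ugraph"))
  shell <- shells$shell[graph$ids]
  prof <- lapply(seq_len(shells$k_max), function(k) {
    keep <- which(shell <= k)
    if (!length(keep)) return(c(k, 0L, 0L))
    sub <- ug_induced(graph, keep)
    sizes <- sort(tabulate(ug_components(sub)), decreasing = TRUE)
    c(k, sizes[1], if (length(sizes) > 1L) sizes[2] else 0L)
  })
  prof <- as.data.frame(do.call(rbind, prof))
  names(prof) <- c("k", "largest", "second")
  prof
}

#' Select the core threshold from a crust profile
#'
#' Operationalises the crust-component crossover rule: k_star is the k
#' maximising the jump in the largest crust component,
#' Delta(k) = largest(k) - largest(k - 1), among those k at which the
#' second-largest component does not grow (second(k) <= second(k - 1)). If
#' no k satisfies the second condition the unconstrained argmax of Delta is
#' used. Ties are broken toward the smallest k. The network core is then
#' the k_star-core (nodes with shell index >= k_star) and the periphery the
#' (k_star - 1)-crust.
#'
#' @param profile `data.frame` from [crust_component_profile()].
#' @return A list with `k_star` and `degenerate` (TRUE when the profile has
#'   a single k).
#' @export
select_core_threshold <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("k", "largest", "second") %in% names(profile)))
  if (!nrow(profile)) cn_stop("empty crust profile", "citenet_input_error")
  profile <- profile[order(profile$k), , drop = FALSE]
  if (nrow(profile) == 1L) {
    return(list(k_star = profile$k[1], degenerate = TRUE))
  }
  ks <- profile$k[-1]
  delta <- diff(profile$largest)
  drop_ok <- diff(profile$second) <= 0
  cand <- if (any(drop_ok)) which(drop_ok) else seq_along(ks)
  best <- cand[which.max(delta[cand])]
  list(k_star = ks[best], degenerate = FALSE)
}

#' Core/periphery assignment of a network
#'
#' Runs the full core-identification sequence: k-shell decomposition of the
#' undirected view, crust component profile, crossover threshold selection,
#' and the induced split into the k_star-core and the (k_star - 1)-crust
#' periphery, together with the core's propagation coverage.
#'
#' @param network A `citation_network`.
#' @return A list with `k_star`, `core_nodes`, `periphery_nodes`,
#'   `coverage`, `shells` and `profile`.
#' @export
core_assignment <- function(network) {
  stopifnot(inherits(network, "citation_network"))
  g <- undirected_view(network)
  shells <- k_shell_decomposition(g)
  profile <- crust_component_profile(g, shells)
  sel <- select_core_threshold(profile)
  core <- names(shells$shell)[shells$shell >= sel$k_star]
  periph <- names(shells$shell)[shells$shell < sel$k_star]
  list(k_star = sel$k_star,
       core_nodes = core,
       periphery_nodes = periph,
       coverage = core_coverage(network, core),
       shells = shells,
       profile = profile)
}

#' Propagation coverage of a core
#'
#' Fraction of all network nodes that are in the core or share at least one
#' edge (in either direction) with a core node.
#'
#' @param network A `citation_network`.
#' @param core Character vector of core node ids (subset of network nodes).
#' @return Fraction in [0, 1]; 0 for an empty core.
#' @export
core_coverage <- function(network, core) {
  stopifnot(inherits(network, "citation_network"))
  if (!length(core)) return(0)
  if (!all(core %in% network$nodes$id)) {
    cn_stop("core contains ids not in the network", "citenet_input_error")
  }
  touch <- network$edges$from %in% core | network$edges$to %in% core
  covered <- union(core,
                   unique(c(network$edges$from[touch],
                            network$edges$to[touch])))
  length(covered) / nrow(network$nodes)
}

#' Cross-country citation matrix of the core
#'
#' Aggregates core-internal citation weights to the country level, excluding
#' domestic (diagonal) citations, and orders rows and columns by descending
#' total citations so the strongest flows sit in the upper-left corner.
#'
#' @param network A `citation_network`.
#' @param core Character vector of core node ids.
#' @return Numeric matrix over the core's countries.
#' @export
core_country_matrix <- function(network, core) {
  stopifnot(inherits(network, "citation_network"))
  nodes <- network$nodes[network$nodes$id %in% core, , drop = FALSE]
  if (anyNA(nodes$country)) {
    cn_stop("core nodes must carry country codes", "citenet_input_error")
  }
  countries <- sort(unique(nodes$country))
  mat <- matrix(0, length(countries), length(countries),
                dimnames = list(countries, countries))
  e <- network$edges
  e <- e[e$from %in% core & e$to %in% core, , drop = FALSE]
  if (nrow(e)) {
    fc <- nodes$country[match(e$from, nodes$id)]
    tc <- nodes$country[match(e$to, nodes$id)]
    keep <- fc != tc
    for (i in which(keep)) {
      mat[fc[i], tc[i]] <- mat[fc[i], tc[i]] + e$weight[i]
    }
  }
  tot <- rowSums(mat) + colSums(mat)
  ord <- order(-tot, names(tot))
  mat[ord, ord, drop = FALSE]
}
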