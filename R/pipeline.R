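CITENET_SCHEMA_VERSION <- 1L

#' Run the full single-stage analysis
#'
#' Executes the whole analysis sequence on one citation network: overall
#' metrics, complementary cumulative degree distribution with power-law
#' fit, small-world statistics, k-shell decomposition with crust-crossover
#' core selection and coverage, Girvan-Newman partitions of the sizable
#' peripheral components, country aggregation, and per-node scores
#' (normalised degree, PageRank with the corpus-estimated damping factor,
#' activity and influence shares). Analysis is deterministic: no stage
#' draws random numbers.
#'
#' @param network A `citation_network`, or the path to an edge table (then
#'   `node_path` must be given and the network is loaded with
#'   [read_network()]).
#' @param node_path Node-table path when `network` is an edge-table path.
#' @param corpus Optional corpus summary (fields `n_reports`,
#'   `n_citation_connections`) used to estimate the damping factor.
#' @param d Damping factor used when no corpus is supplied.
#' @param min_community_component Smallest peripheral component size that is
#'   run through community detection.
#' @param stage_label Label recorded in the report.
#' @return A list of class `stage_report`.
#' @export
run_stage <- function(network, node_path = NULL, corpus = NULL, d = 0.13,
                      min_community_component = 6L, stage_label = NULL) {
  inputs <- list()
  if (is.character(network)) {
    if (is.null(node_path)) {
      cn_stop("node_path is required when loading from an edge table",
              "citenet_input_error")
    }
    inputs <- list(edge_table = unname(tools::md5sum(network)),
                   node_table = unname(tools::md5sum(node_path)))
    network <- read_network(network, node_path,
                            stage_label = stage_label %||% "")
  }
  stopifnot(inherits(network, "citation_network"))
  if (!is.null(stage_label)) network$stage_label <- stage_label
  if (nrow(network$nodes) == 0L) {
    cn_stop("stage input produced an empty network", "citenet_input_error")
  }

  g <- undirected_view(network)
  overall <- overall_metrics(network)
  ccdf <- complementary_cumulative_distribution(g)
  power_law <- tryCatch(fit_power_law(ccdf),
                        citenet_degenerate_fit_error = function(e) {
                          list(skipped = conditionMessage(e))
                        })
  small_world <- small_world_stats(g)
  core <- core_assignment(network)

  ## community detection on sizable peripheral components; when the core
  ## swallows the whole network (small inputs) fall back to the full graph
  partition_components <- function(sub) {
    out <- list()
    comp <- ug_components(sub)
    for (cid in seq_len(max(comp))) {
      members <- which(comp == cid)
      if (length(members) < min_community_component) next
      cg <- ug_induced(sub, members)
      if (cg$m == 0L) next
      part <- best_partition(cg)
      out[[length(out) + 1L]] <-
        list(component_size = length(members),
             q = part$q,
             n_communities = length(part$communities),
             communities = part$communities)
    }
    out
  }
  periph_idx <- match(core$periphery_nodes, g$ids)
  communities <- if (length(periph_idx)) {
    partition_components(ug_induced(g, periph_idx))
  } else list()
  if (!length(communities) && !length(periph_idx) && g$m > 0L) {
    communities <- partition_components(g)
  }

  dest <- if (!is.null(corpus)) estimate_damping_factor(corpus) else NULL
  d_used <- if (!is.null(dest)) dest$d else d
  pr <- pagerank(network, d = d_used)
  scores <- if (nrow(network$nodes) >= 2L && overall$total_weight > 0) {
    node_shares(network, pagerank = pr)
  } else NULL

  structure(list(
    schema_version = CITENET_SCHEMA_VERSION,
    stage_label = network$stage_label,
    inputs = inputs,
    overall = overall,
    power_law = power_law,
    small_world = small_world,
    shells = list(k_max = core$shells$k_max,
                  sizes = as.list(table(core$shells$shell))),
    core = list(k_star = core$k_star,
                n_core = length(core$core_nodes),
                n_periphery = length(core$periphery_nodes),
                coverage = core$coverage,
                core_nodes = core$core_nodes),
    communities = communities,
    country_matrix = aggregate_by_country(network),
    damping = dest %||% list(d = d, numerator = NA, denominator = NA),
    scores = scores,
    network = network
  ), class = "stage_report")
}

#' Compare two stage reports
#'
#' Merges two [run_stage()] reports and appends the cross-stage comparison
#' of outlet and country shares together with network and core size ratios.
#'
#' @param report1,report2 Stage reports (same schema version).
#' @return A list of class `analysis_report` with elements `stage1`,
#'   `stage2` and `comparison`.
#' @export
run_comparison <- function(report1, report2) {
  stopifnot(inherits(report1, "stage_report"),
            inherits(report2, "stage_report"))
  if (!identical(report1$schema_version, report2$schema_version)) {
    cn_stop("stage reports have mismatched schema versions",
            "citenet_input_error")
  }
  comparison <- compare_stages(report1$scores, report2$scores,
                               report1$network, report2$network,
                               core1 = report1$core$core_nodes,
                               core2 = report2$core$core_nodes)
  structure(list(schema_version = report1$schema_version,
                 stage1 = report1, stage2 = report2,
                 comparison = comparison),
            class = "analysis_report")
}

#' @export
print.stage_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("stage_report [%s]\n", x$stage_label))
  cat(sprintf("  nodes %d | edges %d | weight %d | density %s | components %d | largest %d\n",
              o$n_nodes, o$n_edges, o$total_weight,
              format(round_report(o$density, 3)), o$n_components,
              o$largest_component_size))
  if (is.null(x$power_law$skipped)) {
    cat(sprintf("  power law: F(n) = %.3f n^-%.3f (r2 = %.3f)\n",
                x$power_law$a, x$power_law$b, x$power_law$r_squared))
  }
  cat(sprintf("  path length %.3f | clustering %.3f\n",
              x$small_world$characteristic_path_length,
              x$small_world$average_local_clustering))
  cat(sprintf("  shells: %d | core: %d-core, %d nodes, coverage %.0f%%\n",
              x$shells$k_max, x$core$k_star, x$core$n_core,
              100 * x$core$coverage))
  if (length(x$communities)) {
    qs <- vapply(x$communities, function(cc) cc$q, numeric(1))
    cat(sprintf("  peripheral components partitioned: %d (Q = %s)\n",
                length(qs), paste(sprintf("%.3f", qs), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
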