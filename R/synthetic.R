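#' Configuration for the synthetic media-system generator
#'
#' Bundles and validates every knob of the generator: the size and country
#' structure of the media system, the preferential-attachment backbone, the
#' planted dense core, the planted peripheral community blocks, and the
#' report corpus. All stochastic draws downstream are driven by the single
#' `seed`.
#'
#' @param n_outlets Number of media outlets.
#' @param n_countries Number of countries; sizes follow a Zipf-like rank
#'   distribution with exponent `country_size_skew`.
#' @param country_size_skew Positive Zipf exponent of country sizes.
#' @param attachment_edges Edges added per new node by preferential
#'   attachment (0 disables the backbone).
#' @param within_country_affinity Probability that a backbone edge endpoint
#'   is rewired to a same-country outlet.
#' @param planted_core_size Number of outlets densified into a deep-shell
#'   core (0 disables the core).
#' @param planted_communities List of `c(size, p_in, p_out)` triples: block
#'   size, internal edge probability, external edge probability (between
#'   nodes of different blocks).
#' @param n_reports Number of reports in the synthetic corpus.
#' @param citation_prob Probability that a report cites an external outlet
#'   (the ground-truth damping factor d).
#' @param weight_mean Mean citation multiplicity; weights are drawn as
#'   1 + a geometric variate with mean `weight_mean - 1`.
#' @param seed Integer seed driving all randomness.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_outlets = 300L,
                             n_countries = 30L,
                             country_size_skew = 1.2,
                             attachment_edges = 2L,
                             within_country_affinity = 0.3,
                             planted_core_size = 0L,
                             planted_communities = list(),
                             n_reports = 10000L,
                             citation_prob = 0.13,
                             weight_mean = 3,
                             seed = 1L) {
  cfg <- list(
    n_outlets = check_count(n_outlets, "n_outlets", min = 1L),
    n_countries = check_count(n_countries, "n_countries", min = 1L),
    country_size_skew = country_size_skew,
    attachment_edges = check_count(attachment_edges, "attachment_edges"),
    within_country_affinity = check_prob(within_country_affinity,
                                         "within_country_affinity"),
    planted_core_size = check_count(planted_core_size, "planted_core_size"),
    planted_communities = planted_communities,
    n_reports = check_count(n_reports, "n_reports"),
    citation_prob = check_prob(citation_prob, "citation_prob"),
    weight_mean = weight_mean,
    seed = check_count(seed, "seed"))
  if (!is.numeric(country_size_skew) || country_size_skew <= 0) {
    cn_stop("field 'country_size_skew' must be a positive real",
            "citenet_config_error")
  }
  if (!is.numeric(weight_mean) || weight_mean < 1) {
    cn_stop("field 'weight_mean' must be >= 1", "citenet_config_error")
  }
  if (cfg$planted_core_size > cfg$n_outlets) {
    cn_stop("field 'planted_core_size' exceeds n_outlets",
            "citenet_config_error")
  }
  sizes <- vapply(planted_communities, function(b) b[[1]], numeric(1))
  if (length(sizes)) {
    probs <- unlist(lapply(planted_communities, function(b) b[2:3]))
    if (any(probs < 0 | probs > 1)) {
      cn_stop("field 'planted_communities' probabilities must be in [0, 1]",
              "citenet_config_error")
    }
    if (sum(sizes) > cfg$n_outlets) {
      cn_stop("field 'planted_communities' sizes sum above n_outlets",
              "citenet_config_error")
    }
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic media system
#'
#' Draws `n_outlets` outlets with country labels sampled from a Zipf-like
#' country-size distribution (rank-j country has probability proportional to
#' j^-skew). Country codes are drawn from the real ISO 3166-1 alpha-2 pool
#' so the continent lookup applies to synthetic systems too. Deterministic
#' given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with `outlets` (a [media_outlets()] table) and
#'   `ground_truth` (`data.frame` id/community/core plus attribute `true_d`).
#' @export
generate_media_system <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  lut <- country_continents()
  if (config$n_countries > nrow(lut)) {
    cn_stop("field 'n_countries' exceeds the available country-code pool",
            "citenet_config_error")
  }
  codes <- sample(lut$code, config$n_countries)
  p <- seq_len(config$n_countries)^(-config$country_size_skew)
  p <- p / sum(p)
  country <- codes[sample.int(config$n_countries, config$n_outlets,
                              replace = TRUE, prob = p)]
  ids <- sprintf("M%04d", seq_len(config$n_outlets))
  outlets <- media_outlets(id = ids,
                           name = sprintf("Outlet %04d", seq_len(config$n_outlets)),
                           country = country)
  gt <- data.frame(id = ids, community = NA_integer_, core = FALSE,
                   stringsAsFactors = FALSE)
  attr(gt, "true_d") <- config$citation_prob
  list(outlets = outlets, ground_truth = gt)
}

#' Generate a synthetic citation network
#'
#' Builds a directed weighted citation network with the structure of a real
#' media system: a preferential-attachment backbone (heavy-tailed degree
#' distribution; new outlets cite established ones in proportion to their
#' connectivity), endpoints rewired to same-country outlets with probability
#' `within_country_affinity` (country-affine clustering), a planted core of
#' high-degree outlets densified until every core member has a high
#' core-internal degree (guaranteeing a deep k-shell), and planted community
#' blocks with given internal/external edge probabilities. Citation
#' multiplicities are 1 + geometric draws with mean `weight_mean - 1`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `network` (a `citation_network`), `outlets`,
#'   `ground_truth` (community label and core flag per outlet, attribute
#'   `true_d`).
#' @export
generate_citation_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sys <- generate_media_system(config)      # seeds the RNG
  outlets <- sys$outlets
  gt <- sys$ground_truth
  n <- config$n_outlets
  m <- config$attachment_edges

  from <- integer(0)
  to <- integer(0)

  ## preferential-attachment backbone: node v cites m earlier outlets chosen
  ## proportionally to their current (undirected) degree
  if (m > 0L && n > m + 1L) {
    pool <- integer(0)                      # endpoint multiset
    init <- seq_len(m + 1L)
    for (v in init) {
      for (u in init[init < v]) {
        from <- c(from, v); to <- c(to, u)
        pool <- c(pool, v, u)
      }
    }
    for (v in (m + 2L):n) {
      targets <- integer(0)
      while (length(targets) < m) {
        cand <- pool[sample.int(length(pool), 1L)]
        if (cand != v && !cand %in% targets) targets <- c(targets, cand)
      }
      from <- c(from, rep(v, m))
      to <- c(to, targets)
      pool <- c(pool, rep(v, m), targets)
    }
    ## country-affine rewiring of citation targets
    if (config$within_country_affinity > 0) {
      ctry <- outlets$country
      rewire <- stats::runif(length(from)) < config$within_country_affinity
      for (i in which(rewire)) {
        same <- which(ctry == ctry[from[i]])
        same <- same[same != from[i]]
        if (length(same)) to[i] <- same[sample.int(length(same), 1L)]
      }
    }
  }

  ## planted dense core on the highest-degree backbone nodes
  if (config$planted_core_size > 1L) {
    s <- config$planted_core_size
    deg <- tabulate(c(from, to), nbins = n)
    core <- order(-deg, seq_len(n))[seq_len(s)]
    gt$core[core] <- TRUE
    target <- max(2L, ceiling(0.6 * (s - 1L)))
    repeat {
      sub <- (from %in% core) & (to %in% core)
      indeg <- tabulate(c(from[sub], to[sub]), nbins = n)
      pairs <- paste(pmin(from[sub], to[sub]), pmax(from[sub], to[sub]))
      deficient <- core[indeg[core] < target]
      if (!length(deficient)) break
      v <- deficient[1L]
      others <- setdiff(core, v)
      others <- others[!paste(pmin(v, others), pmax(v, others)) %in% pairs]
      if (!length(others)) break
      u <- others[sample.int(length(others), 1L)]
      if (stats::runif(1) < 0.5) {
        from <- c(from, v); to <- c(to, u)
      } else {
        from <- c(from, u); to <- c(to, v)
      }
    }
  }

  ## planted community blocks among non-core outlets, country-affine
  blocks <- config$planted_communities
  if (length(blocks)) {
    avail <- setdiff(seq_len(n), which(gt$core))
    for (b in seq_along(blocks)) {
      size <- as.integer(blocks[[b]][[1]])
      p_in <- blocks[[b]][[2]]
      if (size > length(avail)) {
        cn_stop("planted community does not fit among non-core outlets",
                "citenet_generation_error")
      }
      ## prefer one country's unallocated outlets to make the block affine
      tab <- sort(table(outlets$country[avail]), decreasing = TRUE)
      members <- integer(0)
      for (cc in names(tab)) {
        take <- avail[outlets$country[avail] == cc]
        members <- c(members, utils::head(take, size - length(members)))
        if (length(members) == size) break
      }
      avail <- setdiff(avail, members)
      gt$community[members] <- b
      if (size > 1L && p_in > 0) {
        prs <- utils::combn(members, 2L)
        sel <- which(stats::runif(ncol(prs)) < p_in)
        for (i in sel) {
          a <- prs[, i]
          if (stats::runif(1) < 0.5) a <- rev(a)
          from <- c(from, a[1]); to <- c(to, a[2])
        }
      }
    }
    ## external edges between nodes of different blocks
    assigned <- which(!is.na(gt$community))
    if (length(assigned) > 1L) {
      prs <- utils::combn(assigned, 2L)
      diffb <- gt$community[prs[1, ]] != gt$community[prs[2, ]]
      p_out <- vapply(seq_len(ncol(prs)), function(i) {
        if (!diffb[i]) return(0)
        mean(c(blocks[[gt$community[prs[1, i]]]][[3]],
               blocks[[gt$community[prs[2, i]]]][[3]]))
      }, numeric(1))
      sel <- which(stats::runif(ncol(prs)) < p_out)
      for (i in sel) {
        a <- prs[, i]
        if (stats::runif(1) < 0.5) a <- rev(a)
        from <- c(from, a[1]); to <- c(to, a[2])
      }
    }
  }

  ## weights: positive integers around weight_mean
  if (length(from)) {
    w <- if (config$weight_mean > 1) {
      1L + stats::rgeom(length(from), prob = 1 / config$weight_mean)
    } else {
      rep(1L, length(from))
    }
    records <- data.frame(citing = outlets$id[from], cited = outlets$id[to],
                          count = w, stringsAsFactors = FALSE)
  } else {
    records <- data.frame(citing = character(), cited = character(),
                          count = integer(), stringsAsFactors = FALSE)
  }
  network <- build_network(records, outlets, stage_label = "synthetic")
  attr(gt, "true_d") <- config$citation_prob
  list(network = network, outlets = outlets, ground_truth = gt)
}

#' Generate a synthetic report corpus
#'
#' Emulates a news corpus over an existing citation network: each of
#' `n_reports` reports is published by a random outlet and cites an external
#' outlet with probability `citation_prob` (the ground-truth damping
#' factor). The summary totals are consistent with the record list, so
#' [estimate_damping_factor()] on the summary recovers `citation_prob` up
#' to binomial sampling error.
#'
#' @param config A [synthetic_config()].
#' @param network The `citation_network` the reports cite into.
#' @return A list with `summary` (fields `n_reports`,
#'   `n_citation_connections`, `stage_label`) and `records` (`data.frame`
#'   report_id/citing/cited).
#' @export
generate_report_corpus <- function(config, network) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(network, "citation_network"))
  set.seed(config$seed + 1L)
  ids <- network$nodes$id
  if (length(ids) < 2L) {
    cn_stop("corpus generation needs a network with at least 2 outlets",
            "citenet_input_error")
  }
  nr <- config$n_reports
  publisher <- ids[sample.int(length(ids), nr, replace = TRUE)]
  cites <- stats::runif(nr) < config$citation_prob
  idx <- which(cites)
  cited <- character(length(idx))
  out_nb <- split(network$edges$to, network$edges$from)
  for (j in seq_along(idx)) {
    p <- publisher[idx[j]]
    nb <- out_nb[[p]]
    cited[j] <- if (length(nb)) {
      nb[sample.int(length(nb), 1L)]
    } else {
      others <- ids[ids != p]
      others[sample.int(length(others), 1L)]
    }
  }
  records <- data.frame(report_id = idx, citing = publisher[idx],
                        cited = cited, stringsAsFactors = FALSE)
  list(summary = list(n_reports = nr,
                      n_citation_connections = nrow(records),
                      stage_label = network$stage_label),
       records = records)
}
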