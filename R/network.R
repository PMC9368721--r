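#' Media outlet table
#'
#' Canonical node metadata for a citation network: one row per outlet with a
#' unique identifier, a display name, a two-letter uppercase country code and
#' (optionally) a continent label. Missing regions are filled from the
#' country-to-continent lookup shipped with the package.
#'
#' @param id Character vector of unique outlet identifiers.
#' @param name Outlet display names (defaults to `id`).
#' @param country Two-letter uppercase country codes (ISO 3166-1 alpha-2).
#' @param region Continent labels; `NA` entries are filled from
#'   [country_continents()].
#' @return A `data.frame` with columns `id`, `name`, `country`, `region`.
#' @export
media_outlets <- function(id, name = id, country, region = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    cn_stop("outlet ids must be unique", "citenet_input_error")
  }
  country <- toupper(as.character(country))
  bad <- nchar(country) != 2L
  if (any(bad, na.rm = TRUE)) {
    cn_stop(sprintf("country codes must be two letters (offending: %s)",
                    paste(utils::head(country[bad], 3), collapse = ", ")),
            "citenet_input_error")
  }
  out <- data.frame(id = id, name = as.character(name), country = country,
                    region = as.character(region), stringsAsFactors = FALSE)
  if (anyNA(out$region)) {
    lut <- country_continents()
    miss <- is.na(out$region)
    out$region[miss] <- lut$continent[match(out$country[miss], lut$code)]
  }
  out
}

#' Build a citation network from citation records
#'
#' Assembles a simple directed weighted graph from `(citing, cited, count)`
#' records. Duplicate ordered pairs are merged by summing their counts,
#' self-citations are rejected, and outlets that appear in no record are
#' excluded from the network (only outlets that cite or are cited enter the
#' graph).
#'
#' @param records `data.frame` with columns `citing`, `cited`, `count`
#'   (positive integers; `count` defaults to 1 if absent).
#' @param outlets Outlet table as returned by [media_outlets()]; every record
#'   endpoint must resolve to an outlet id.
#' @param stage_label Free-text label attached to the network (e.g. an
#'   observation-window name).
#' @return An object of class `citation_network`: a list with `nodes` (outlet
#'   rows that participate in at least one edge), `edges` (`from`, `to`,
#'   `weight`) and `stage_label`.
#' @export
build_network <- function(records, outlets, stage_label = "") {
  stopifnot(is.data.frame(outlets), all(c("id", "country") %in% names(outlets)))
  if (is.null(records) || nrow(records) == 0L) {
    return(structure(list(nodes = outlets[0, , drop = FALSE],
                          edges = data.frame(from = character(),
                                             to = character(),
                                             weight = integer(),
                                             stringsAsFactors = FALSE),
                          stage_label = stage_label),
                     class = "citation_network"))
  }
  stopifnot(all(c("citing", "cited") %in% names(records)))
  if (is.null(records$count)) records$count <- 1L
  if (any(records$count < 1 | records$count != floor(records$count))) {
    cn_stop("citation counts must be positive integers", "citenet_input_error")
  }
  unresolved <- setdiff(unique(c(records$citing, records$cited)), outlets$id)
  if (length(unresolved)) {
    cn_stop(sprintf("citation record endpoint(s) not in outlet table: %s",
                    paste(utils::head(unresolved, 5), collapse = ", ")),
            "citenet_input_error")
  }
  if (any(records$citing == records$cited)) {
    cn_stop("self-citations are not permitted in a citation network",
            "citenet_input_error")
  }
  agg <- stats::aggregate(count ~ citing + cited, data = records, FUN = sum)
  agg <- agg[order(agg$citing, agg$cited), , drop = FALSE]
  used <- unique(c(agg$citing, agg$cited))
  nodes <- outlets[outlets$id %in% used, , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(from = agg$citing, to = agg$cited,
                      weight = as.integer(agg$count),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, stage_label = stage_label),
            class = "citation_network")
}

#' @export
print.citation_network <- function(x, ...) {
  cat(sprintf("citation_network%s: %d outlets, %d edges, total weight %d\n",
              if (nzchar(x$stage_label)) paste0(" [", x$stage_label, "]") else "",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Extract citation records from report snippets
#'
#' Scans each report snippet for mentions of outlet names and aliases from a
#' thesaurus and emits one citation record per detected mention, directed
#' from the publishing outlet to the mentioned outlet. Matching is
#' case-insensitive and longest-alias-first, so a short name nested inside a
#' longer one (e.g. "Post" inside "The Washington Post") is not double
#' counted. Self-mentions (an outlet naming itself) are dropped. Reports
#' published by an outlet absent from the thesaurus are skipped and counted
#' in the result metadata.
#'
#' @param reports `data.frame` with columns `report_id`, `outlet_id`
#'   (publisher) and `text` (snippet).
#' @param thesaurus `data.frame` with columns `id` and `alias`: one row per
#'   matchable name (official names and aliases alike).
#' @return A list with `records` (`citing`, `cited`, `count`, one row per
#'   mention, sorted) and `n_skipped_reports`.
#' @export
extract_citations <- function(reports, thesaurus) {
  stopifnot(is.data.frame(reports),
            all(c("report_id", "outlet_id", "text") %in% names(reports)),
            is.data.frame(thesaurus),
            all(c("id", "alias") %in% names(thesaurus)))
  terms <- data.frame(id = as.character(thesaurus$id),
                      alias = tolower(as.character(thesaurus$alias)),
                      stringsAsFactors = FALSE)
  terms <- terms[nzchar(terms$alias), , drop = FALSE]
  if (!nrow(terms)) {
    cn_stop("thesaurus contains no non-empty aliases", "citenet_input_error")
  }
  terms <- terms[order(-nchar(terms$alias)), , drop = FALSE]
  known <- unique(terms$id)

  citing <- character()
  cited <- character()
  skipped <- 0L
  for (i in seq_len(nrow(reports))) {
    pub <- as.character(reports$outlet_id[i])
    if (!pub %in% known) {
      skipped <- skipped + 1L
      next
    }
    txt <- tolower(as.character(reports$text[i]))
    for (j in seq_len(nrow(terms))) {
      hits <- gregexpr(terms$alias[j], txt, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      len <- attr(hits, "match.length")
      ## mask matched spans so shorter aliases nested inside cannot re-match
      for (h in seq_along(hits)) {
        substr(txt, hits[h], hits[h] + len[h] - 1L) <-
          strrep("\x01", len[h])
      }
      tgt <- terms$id[j]
      if (tgt == pub) next                       # self-mention
      citing <- c(citing, rep(pub, length(hits)))
      cited <- c(cited, rep(tgt, length(hits)))
    }
  }
  records <- data.frame(citing = citing, cited = cited,
                        count = rep(1L, length(citing)),
                        stringsAsFactors = FALSE)
  records <- records[order(records$citing, records$cited), , drop = FALSE]
  rownames(records) <- NULL
  if (skipped > 0L) {
    warning(sprintf("%d report(s) skipped: publishing outlet not in thesaurus",
                    skipped))
  }
  list(records = records, n_skipped_reports = skipped)
}

#' Aggregate a citation network to the country level
#'
#' Collapses outlet-to-outlet citation weights into a square country matrix:
#' cell (r, c) holds the total weight of edges from country-r outlets citing
#' country-c outlets; the diagonal holds domestic citations. The total of
#' the matrix equals the total edge weight of the network.
#'
#' @param network A `citation_network`.
#' @return A numeric matrix with country codes as dimnames.
#' @export
aggregate_by_country <- function(network) {
  stopifnot(inherits(network, "citation_network"))
  if (anyNA(network$nodes$country)) {
    cn_stop("all nodes must carry a country code", "citenet_input_error")
  }
  countries <- sort(unique(network$nodes$country))
  mat <- matrix(0, length(countries), length(countries),
                dimnames = list(countries, countries))
  if (nrow(network$edges)) {
    cc <- network$nodes$country[match(network$edges$from, network$nodes$id)]
    tc <- network$nodes$country[match(network$edges$to, network$nodes$id)]
    for (i in seq_along(cc)) {
      mat[cc[i], tc[i]] <- mat[cc[i], tc[i]] + network$edges$weight[i]
    }
  }
  mat
}

#' Country-to-continent lookup
#'
#' Returns the two-letter country code to continent table shipped with the
#' package (`inst/extdata/country_continents.csv`).
#'
#' @return `data.frame` with columns `code` and `continent`.
#' @export
country_continents <- function() {
  path <- system.file("extdata", "country_continents.csv", package = "citenet")
  ## na.strings = NULL: "NA" is Namibia, not a missing value
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = NULL)
}
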