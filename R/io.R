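#' Read and write citation-network tables
#'
#' Edge lists use the header `source,target,weight`; node tables use
#' `id,name,country,region`; thesauri use `id,name,alias` (one row per
#' matchable alias). All files are plain comma-separated text.
#'
#' @param network A `citation_network`.
#' @param path File path.
#' @return `write_*` return the path invisibly; readers return data frames
#'   or a `citation_network`.
#' @name citenet-io
NULL

#' @rdname citenet-io
#' @export
write_edge_table <- function(network, path) {
  df <- data.frame(source = network$edges$from, target = network$edges$to,
                   weight = network$edges$weight)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname citenet-io
#' @export
write_node_table <- function(network, path) {
  utils::write.csv(network$nodes, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname citenet-io
#' @param edge_path,node_path Paths to an edge table and a node table.
#' @param stage_label Label for the rebuilt network.
#' @export
read_network <- function(edge_path, node_path, stage_label = "") {
  edges <- utils::read.csv(edge_path, stringsAsFactors = FALSE,
                           na.strings = NULL)
  nodes <- utils::read.csv(node_path, stringsAsFactors = FALSE,
                           na.strings = NULL)
  if (!all(c("source", "target", "weight") %in% names(edges))) {
    cn_stop("edge table must have columns source,target,weight",
            "citenet_input_error")
  }
  outlets <- media_outlets(id = nodes$id, name = nodes$name,
                           country = nodes$country,
                           region = if ("region" %in% names(nodes)) {
                             nodes$region
                           } else NA_character_)
  records <- data.frame(citing = as.character(edges$source),
                        cited = as.character(edges$target),
                        count = edges$weight, stringsAsFactors = FALSE)
  build_network(records, outlets, stage_label = stage_label)
}

#' @rdname citenet-io
#' @export
read_thesaurus <- function(path) {
  th <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "alias") %in% names(th))) {
    cn_stop("thesaurus must have columns id,name,alias", "citenet_input_error")
  }
  if ("name" %in% names(th)) {
    extra <- unique(th[, c("id", "name")])
    names(extra)[2] <- "alias"
    th <- unique(rbind(th[, c("id", "alias")], extra))
  }
  th[order(th$id, th$alias), , drop = FALSE]
}

## internal: minimal XML text escaping for the GraphML writer
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

#' Write a citation network as GraphML
#'
#' Emits a directed GraphML graph with `name`, `country` and `region` node
#' attributes and a `weight` edge attribute.
#'
#' @param network A `citation_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(network, path) {
  n <- network$nodes
  e <- network$edges
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="country" attr.type="string"/>',
    '  <key id="d2" for="node" attr.name="region" attr.type="string"/>',
    '  <key id="d3" for="edge" attr.name="weight" attr.type="int"/>',
    sprintf('  <graph id="%s" edgedefault="directed">',
            xml_escape(network$stage_label)))
  if (nrow(n)) {
    lines <- c(lines, sprintf(
      paste0('    <node id="%s"><data key="d0">%s</data>',
             '<data key="d1">%s</data><data key="d2">%s</data></node>'),
      xml_escape(n$id), xml_escape(n$name), xml_escape(n$country),
      xml_escape(ifelse(is.na(n$region), "", n$region))))
  }
  if (nrow(e)) {
    lines <- c(lines, sprintf(
      '    <edge source="%s" target="%s"><data key="d3">%d</data></edge>',
      xml_escape(e$from), xml_escape(e$to), e$weight))
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GraphML citation network
#'
#' Parses a directed GraphML file written by [write_graphml()] (or any
#' GraphML with string node attributes `name`/`country`/`region` and an
#' integer edge attribute `weight`).
#'
#' @param path GraphML file path.
#' @return A `citation_network`.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  keymap <- setNames(xml2::xml_attr(keys, "attr.name"),
                     xml2::xml_attr(keys, "id"))
  graph <- xml2::xml_find_first(doc, ".//graph")
  stage <- xml2::xml_attr(graph, "id")
  if (is.na(stage)) stage <- ""

  node_attr <- function(node, attr_name) {
    data <- xml2::xml_find_all(node, "./data")
    kk <- keymap[xml2::xml_attr(data, "key")]
    v <- xml2::xml_text(data)[match(attr_name, kk)]
    if (length(v)) v else NA_character_
  }
  nodes <- xml2::xml_find_all(graph, "./node")
  ids <- xml2::xml_attr(nodes, "id")
  nm <- vapply(nodes, node_attr, character(1), attr_name = "name")
  ct <- vapply(nodes, node_attr, character(1), attr_name = "country")
  rg <- vapply(nodes, node_attr, character(1), attr_name = "region")
  outlets <- media_outlets(id = ids,
                           name = ifelse(is.na(nm), ids, nm),
                           country = ct, region = rg)
  edges <- xml2::xml_find_all(graph, "./edge")
  w <- vapply(edges, function(ed) {
    data <- xml2::xml_find_all(ed, "./data")
    kk <- keymap[xml2::xml_attr(data, "key")]
    v <- xml2::xml_text(data)[match("weight", kk)]
    if (length(v) && !is.na(v)) as.integer(v) else 1L
  }, integer(1))
  records <- data.frame(citing = xml2::xml_attr(edges, "source"),
                        cited = xml2::xml_attr(edges, "target"),
                        count = w, stringsAsFactors = FALSE)
  build_network(records, outlets, stage_label = stage)
}

#' Read a generator/analysis configuration file
#'
#' Reads a YAML key-value file and, for the keys it recognises, forwards
#' them to [synthetic_config()].
#'
#' @param path YAML file path.
#' @return A [synthetic_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    cn_stop(sprintf("unknown configuration field(s): %s",
                    paste(unknown, collapse = ", ")),
            "citenet_config_error")
  }
  if (!is.null(vals$planted_communities)) {
    vals$planted_communities <- lapply(vals$planted_communities, unlist)
  }
  do.call(synthetic_config, vals)
}

#' Write an analysis report as JSON
#'
#' @param report A stage or comparison report (see [run_stage()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write a country citation matrix as CSV
#'
#' @param mat Matrix from [aggregate_by_country()] or
#'   [core_country_matrix()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_country_matrix <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE)
  invisible(path)
}
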