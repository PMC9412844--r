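# Network export in Cytoscape-compatible formats (GraphML, SIF, edge list)
# and community/topology report serialisation.

#' Export an omics network
#'
#' GraphML carries the `omics_type` node attribute and the provenance
#' (threshold `t`, `group`, `mode`) as graph attributes and round-trips
#' losslessly; SIF uses the interaction label `cor`, writing isolated nodes
#' as single-token lines; `edgelist` is a two-column TSV (`source`,
#' `target`).
#'
#' @param net An `omics_network`.
#' @param path Output file path.
#' @param format `"graphml"`, `"sif"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "edgelist")) {
  stopifnot(inherits(net, "omics_network"))
  if (!is.character(format) || !(format[1] %in% c("graphml", "sif", "edgelist"))) {
    stop("unknown export format: ", format[1], call. = FALSE)
  }
  format <- match.arg(format)
  g <- net$graph
  if (format == "graphml") {
    p <- net$provenance
    igraph::graph_attr(g, "group") <- as.character(p$group)
    igraph::graph_attr(g, "t") <- as.numeric(p$t)
    igraph::graph_attr(g, "mode") <- as.character(p$mode)
    igraph::graph_attr(g, "n_samples") <- as.numeric(p$n_samples)
    igraph::graph_attr(g, "method") <- as.character(p$method)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    e <- network_edges(net)
    lines <- if (nrow(e) > 0) paste(e[, 1], "cor", e[, 2]) else character(0)
    iso <- setdiff(igraph::V(g)$name, unique(as.vector(e)))
    writeLines(c(lines, iso), path)
  } else {
    e <- network_edges(net)
    df <- data.frame(source = e[, 1], target = e[, 2],
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Import a GraphML network exported by [export_network()]
#'
#' @param path GraphML file.
#' @return An `omics_network` with provenance restored.
#' @export
import_network_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  ga <- igraph::graph_attr(g)
  prov <- list(
    group = if (!is.null(ga$group)) ga$group else NA_character_,
    n_samples = if (!is.null(ga$n_samples)) as.integer(ga$n_samples) else NA_integer_,
    t = if (!is.null(ga$t)) as.numeric(ga$t) else NA_real_,
    mode = if (!is.null(ga$mode)) ga$mode else NA_character_,
    method = if (!is.null(ga$method)) ga$method else NA_character_)
  for (a in names(ga)) g <- igraph::delete_graph_attr(g, a)
  structure(list(graph = g, provenance = prov), class = "omics_network")
}

#' Serialise a community report to JSON
#'
#' Writes `{k, communities: [[node ids]], bridge_nodes: [{id, omics_type,
#' membership}]}`.
#'
#' @param cs A `community_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_community_report <- function(cs, path) {
  stopifnot(inherits(cs, "community_set"))
  ov <- community_overlap(cs)
  obj <- list(k = cs$k,
              communities = cs$communities,
              bridge_nodes = ov$bridge_nodes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialise a topology report to JSON
#'
#' @param report A `topology_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_topology_report <- function(report, path) {
  stopifnot(inherits(report, "topology_report"))
  obj <- unclass(report)
  obj$degree_histogram <- list(degree = as.numeric(names(report$degree_histogram)),
                               count = as.integer(report$degree_histogram))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialise an agglomeration map to JSON
#'
#' @param map An `agglomeration_map`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_agglomeration_map <- function(map, path) {
  stopifnot(inherits(map, "agglomeration_map"))
  obj <- list(cut_height = map$cut_height,
              cluster_of = as.list(map$cluster_of),
              pooled_ids = as.list(map$pooled_ids))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
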