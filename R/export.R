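#' Export a network as GraphML
#'
#' Node roles travel as the `role` vertex attribute; the file is readable by
#' Cytoscape and by [read_network_graphml()].
#'
#' @param net A network.
#' @param path Output path (`.graphml`).
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Read back a GraphML network
#'
#' @param path Path written by [write_network_graphml()].
#' @return An undirected igraph with `name` and `role` vertex attributes.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (!"name" %in% igraph::vertex_attr_names(g) &&
      "id" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name <- igraph::V(g)$id
  }
  g
}

#' Export a network in SIF format
#'
#' Simple interaction format: `node <TAB> interaction <TAB> node`, one edge
#' per line; isolated nodes are written as bare single-field lines (the
#' Cytoscape convention).
#'
#' @param net A network.
#' @param path Output path (`.sif`).
#' @param interaction Relation label written in the middle column.
#' @return Invisibly, `path`.
#' @export
write_network_sif <- function(net, path, interaction = "pp") {
  em <- igraph::as_edgelist(net, names = TRUE)
  lines <- character(0)
  if (nrow(em) > 0) {
    lines <- paste(em[, 1], interaction, em[, 2], sep = "\t")
  }
  iso <- igraph::V(net)$name[igraph::degree(net) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Export a network edge list as TSV
#'
#' @param net A network.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_tsv <- function(net, path) {
  em <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(source_id = em[, 1], target_id = em[, 2],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a centrality table as TSV
#'
#' Columns: node, role, degree, betweenness, closeness.
#'
#' @param table A centrality table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_centrality_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
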