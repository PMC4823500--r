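#' Mean-value thresholds for hub selection
#'
#' The three thresholds are the arithmetic means of degree, betweenness, and
#' closeness over all nodes of the network's topology table (unrounded).
#'
#' @param table A centrality table from [centrality_table()].
#' @return Named numeric vector `c(degree=, betweenness=, closeness=)`.
#' @export
compute_thresholds <- function(table) {
  if (is.null(table) || nrow(table) == 0) {
    stop("empty centrality table", call. = FALSE)
  }
  th <- c(degree = mean(table$degree),
          betweenness = mean(table$betweenness),
          closeness = mean(table$closeness))
  message(sprintf(
    "compute_thresholds: degree >= %.2f, betweenness >= %.5f, closeness >= %.4f",
    th["degree"], th["betweenness"], th["closeness"]))
  th
}

#' Select major (hub) nodes
#'
#' A node is major when its degree, betweenness, and closeness all meet or
#' exceed (inclusive) the corresponding threshold.
#'
#' @param table A centrality table.
#' @param thresholds Named vector from [compute_thresholds()].
#' @return Character vector of major-node ids.
#' @export
select_major_nodes <- function(table, thresholds) {
  stopifnot(all(c("degree", "betweenness", "closeness") %in% names(thresholds)),
            all(is.finite(thresholds)))
  sel <- table$degree >= thresholds[["degree"]] &
         table$betweenness >= thresholds[["betweenness"]] &
         table$closeness >= thresholds[["closeness"]]
  table$node[sel]
}

#' Potential drug targets
#'
#' Major nodes that are compound targets (including proteins shared between
#' the compound-target and disease-target sets).
#'
#' @param major Character vector of major-node ids.
#' @param compound_targets Character vector of compound-target ids.
#' @param shared_targets Character vector of shared compound/disease targets.
#' @return Character vector (subset of `major`).
#' @export
potential_targets <- function(major, compound_targets,
                              shared_targets = character()) {
  out <- intersect(major, union(compound_targets, shared_targets))
  if (length(out) == 0) {
    warning("no major node is a compound target", call. = FALSE)
  }
  out
}

#' Hub selection on a network
#'
#' Convenience wrapper: computes the topology table, the mean thresholds,
#' the major-node set, and the potential-target set (major nodes that are
#' compound targets or shared targets, read from the role labels).
#'
#' @param net A network with role labels (normally the PPI expansion
#'   network).
#' @param closeness_method Passed to [centrality_table()].
#' @return A list of class `hub_selection`: `thresholds`, `major_nodes`,
#'   `potential_targets`, `table` (centrality table restricted to major
#'   nodes), `source_network`.
#' @export
hub_selection <- function(net, closeness_method = "wf") {
  tab <- centrality_table(net, closeness_method)
  th <- compute_thresholds(tab)
  major <- select_major_nodes(tab, th)
  roles <- node_roles(net)
  ct <- names(roles)[roles == "COMPOUND_TARGET"]
  sh <- names(roles)[roles == "SHARED_TARGET"]
  pot <- potential_targets(major, ct, sh)
  structure(list(thresholds = th,
                 major_nodes = major,
                 potential_targets = pot,
                 table = tab[tab$node %in% major, , drop = FALSE],
                 source_network = net$name),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat("Hub selection on network '", x$source_network, "'\n", sep = "")
  cat(sprintf("  thresholds: degree >= %.4g, betweenness >= %.4g, closeness >= %.4g\n",
              x$thresholds[["degree"]], x$thresholds[["betweenness"]],
              x$thresholds[["closeness"]]))
  cat("  major nodes:      ", length(x$major_nodes), "\n")
  cat("  potential targets:", length(x$potential_targets), "\n")
  invisible(x)
}

#' Write a hub-selection report
#'
#' Writes a JSON report (thresholds, per-role tallies of major nodes,
#' potential-target list) and a TSV of major nodes with their three index
#' values.
#'
#' @param hubs A `hub_selection`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report list.
#' @export
write_hub_report <- function(hubs, json_path = NULL, tsv_path = NULL) {
  tal <- table(hubs$table$role)
  report <- list(source_network = hubs$source_network,
                 thresholds = as.list(hubs$thresholds),
                 n_major = length(hubs$major_nodes),
                 major_by_role = as.list(setNames(as.integer(tal), names(tal))),
                 n_potential_targets = length(hubs$potential_targets),
                 potential_targets = hubs$potential_targets)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) {
    write.table(hubs$table, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(report)
}
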