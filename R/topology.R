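#' Node degree
#'
#' Number of edges incident to each node of a simple undirected network.
#'
#' @param net A network.
#' @return Named integer vector.
#' @export
node_degree <- function(net) {
  d <- igraph::degree(net, loops = FALSE)
  setNames(as.integer(d), igraph::V(net)$name)
}

#' Normalized node betweenness
#'
#' Fraction of shortest paths between other node pairs that pass through
#' each node, with the standard fractional weighting over tied shortest
#' paths, normalized by (N-1)(N-2)/2 so values lie in \[0,1\]. Pairs in
#' different components contribute nothing. Networks with fewer than three
#' nodes score zero everywhere.
#'
#' @param net A network.
#' @return Named numeric vector in \[0,1\].
#' @export
node_betweenness <- function(net) {
  n <- igraph::vcount(net)
  ids <- igraph::V(net)$name
  if (n < 3) return(setNames(rep(0, n), ids))
  b <- igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(b), ids)
}

#' Normalized closeness
#'
#' For node i with r reachable other nodes at total shortest-path distance
#' S, the component-corrected normalized closeness is
#' (r / (N-1)) * (r / S) (Wasserman-Faust), which reduces to (N-1)/S on a
#' connected network and is well defined on disconnected ones. Isolated
#' nodes (and a single-node network) score 0. `method = "raw"` gives the
#' plain reciprocal 1/S over reachable nodes instead.
#'
#' @param net A network.
#' @param method `"wf"` (component-corrected, default) or `"raw"`.
#' @return Named numeric vector; `"wf"` values lie in \[0,1\].
#' @export
node_closeness <- function(net, method = c("wf", "raw")) {
  method <- match.arg(method)
  n <- igraph::vcount(net)
  ids <- igraph::V(net)$name
  if (n <= 1) return(setNames(rep(0, n), ids))
  dm <- igraph::distances(net)
  out <- vapply(seq_len(n), function(i) {
    d <- dm[i, -i]
    fin <- d[is.finite(d)]
    r <- length(fin)
    if (r == 0) return(0)
    s <- sum(fin)
    if (method == "wf") (r / (n - 1)) * (r / s) else 1 / s
  }, numeric(1))
  setNames(out, ids)
}

#' Per-node topology table
#'
#' Assembles degree, normalized betweenness, and normalized closeness for
#' every node, with its role label. Deterministic for a fixed network.
#'
#' @param net A network.
#' @param closeness_method Passed to [node_closeness()].
#' @return data.frame with columns `node`, `role`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
centrality_table <- function(net, closeness_method = "wf") {
  ids <- igraph::V(net)$name
  role <- if ("role" %in% igraph::vertex_attr_names(net)) {
    igraph::V(net)$role
  } else rep(NA_character_, length(ids))
  data.frame(node = ids,
             role = role,
             degree = unname(node_degree(net)),
             betweenness = unname(node_betweenness(net)),
             closeness = unname(node_closeness(net, closeness_method)),
             stringsAsFactors = FALSE)
}
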