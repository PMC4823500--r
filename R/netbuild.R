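NODE_ROLES <- c("HERB", "COMPOUND", "COMPOUND_TARGET", "DISEASE_TARGET",
                "SHARED_TARGET", "OTHER_PROTEIN")

# Internal constructor: simple undirected igraph with a 'role' vertex
# attribute and a 'name' graph attribute. Edges given as a 2-column
# character matrix (may be empty).
pharm_network <- function(node_ids, roles, edge_mat, name) {
  stopifnot(length(node_ids) == length(roles),
            all(roles %in% NODE_ROLES),
            !anyDuplicated(node_ids))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_ids), name = node_ids, role = roles)
  if (length(edge_mat) > 0 && nrow(edge_mat) > 0) {
    stopifnot(all(edge_mat %in% node_ids))
    g <- igraph::add_edges(g, t(edge_mat))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g$name <- name
  g
}

#' Node roles of a network
#'
#' @param net A network built by one of the `build_*_network()` functions.
#' @return Named character vector of role labels, one per node.
#' @export
node_roles <- function(net) {
  setNames(igraph::V(net)$role, igraph::V(net)$name)
}

#' Per-role node tally
#'
#' @inheritParams node_roles
#' @return Named integer vector counting nodes per role (present roles only).
#' @export
role_tally <- function(net) {
  r <- table(igraph::V(net)$role)
  setNames(as.integer(r), names(r))
}

#' Build the compound-target bipartite network
#'
#' Links compounds to their protein targets using score-filtered
#' chemical-protein interaction records. Compounds without any surviving
#' interaction are excluded (the "no relevant information" rule), so the
#' network is bipartite over compounds with evidence and their targets.
#'
#' @param compounds data.frame from [read_compound_table()].
#' @param interactions data.frame from [read_interaction_table()] whose
#'   `source_id` are compound ids and `target_id` protein ids.
#' @param name Network name attribute.
#' @return An undirected igraph with roles COMPOUND / COMPOUND_TARGET.
#' @export
build_compound_target_network <- function(compounds, interactions,
                                          name = "compound_target") {
  known <- unique(compounds$compound_id)
  keep <- interactions$source_id %in% known
  inter <- interactions[keep, , drop = FALSE]
  if (nrow(inter) == 0) {
    stop("empty network: no interactions involve a known compound",
         call. = FALSE)
  }
  cps <- unique(inter$source_id)
  tgts <- unique(inter$target_id)
  overlap <- intersect(cps, tgts)
  if (length(overlap) > 0) {
    stop("identifier clash between compounds and targets: ",
         paste(head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  message("build_compound_target_network: ", length(cps), " compounds with ",
          "interactions (of ", length(known), "), ", length(tgts),
          " targets, ", nrow(inter), " edges")
  pharm_network(c(cps, tgts),
                c(rep("COMPOUND", length(cps)),
                  rep("COMPOUND_TARGET", length(tgts))),
                cbind(inter$source_id, inter$target_id),
                name)
}

#' Compound targets of a network or interaction set
#'
#' Distinct protein targets reached by any compound with at least one
#' surviving interaction.
#'
#' @inheritParams build_compound_target_network
#' @return Character vector of target ids.
#' @export
compound_target_ids <- function(compounds, interactions) {
  known <- unique(compounds$compound_id)
  unique(interactions$target_id[interactions$source_id %in% known])
}

#' Build the herb-target-disease network
#'
#' Each herb is linked directly to every compound target reached through any
#' of its compounds (the compounds themselves are collapsed out). Disease
#' targets that are not themselves compound targets are included only if a
#' PPI edge connects them to at least one compound target. Proteins that are
#' both compound and disease targets are labeled SHARED_TARGET. Edges are
#' the herb-target links plus the PPI links between compound targets and
#' disease targets.
#'
#' @inheritParams build_compound_target_network
#' @param disease Target set from [read_disease_targets()].
#' @param ppi Merged, filtered PPI records ([merge_ppi_sources()]).
#' @param name Network name attribute.
#' @return An undirected igraph with roles HERB / COMPOUND_TARGET /
#'   DISEASE_TARGET / SHARED_TARGET.
#' @export
build_herb_target_disease_network <- function(compounds, interactions, disease,
                                              ppi,
                                              name = "herb_target_disease") {
  known <- unique(compounds$compound_id)
  inter <- interactions[interactions$source_id %in% known, , drop = FALSE]
  ct <- unique(inter$target_id)
  dt <- disease$target_ids
  shared <- intersect(ct, dt)
  ct_only <- setdiff(ct, dt)
  dt_only <- setdiff(dt, ct)

  # herb -> target links via that herb's compounds
  herb_edges <- unique(merge(compounds[, c("herb_id", "compound_id")],
                             inter[, c("source_id", "target_id")],
                             by.x = "compound_id", by.y = "source_id")
                       [, c("herb_id", "target_id")])
  herbs <- unique(compounds$herb_id)

  # disease targets retained only if a PPI edge links them to a compound target
  ppi_ct_dt <- ppi[(ppi$source_id %in% ct & ppi$target_id %in% dt) |
                   (ppi$target_id %in% ct & ppi$source_id %in% dt), ,
                   drop = FALSE]
  linked_dt <- intersect(dt_only,
                         unique(c(ppi_ct_dt$source_id, ppi_ct_dt$target_id)))
  dropped <- setdiff(dt_only, linked_dt)
  if (length(dropped) > 0) {
    message("build_herb_target_disease_network: ", length(dropped),
            " disease target(s) without a PPI link to any compound target ",
            "excluded")
  }
  nodes <- c(herbs, ct_only, linked_dt, shared)
  roles <- c(rep("HERB", length(herbs)),
             rep("COMPOUND_TARGET", length(ct_only)),
             rep("DISEASE_TARGET", length(linked_dt)),
             rep("SHARED_TARGET", length(shared)))
  keep_ppi <- ppi_ct_dt$source_id %in% nodes & ppi_ct_dt$target_id %in% nodes
  edge_mat <- rbind(cbind(herb_edges$herb_id, herb_edges$target_id),
                    cbind(ppi_ct_dt$source_id[keep_ppi],
                          ppi_ct_dt$target_id[keep_ppi]))
  net <- pharm_network(nodes, roles, edge_mat, name)
  message("build_herb_target_disease_network: ", igraph::vcount(net),
          " nodes (", length(herbs), " herbs, ", length(ct_only),
          " compound targets, ", length(linked_dt), " disease targets, ",
          length(shared), " shared), ", igraph::ecount(net), " edges")
  net
}

#' Build the PPI first-neighbor expansion network
#'
#' Seeds the network with all compound targets and disease targets, adds
#' every protein directly interacting with a seed, and keeps either the full
#' induced PPI subgraph on that node set (`edges = "induced"`, default) or
#' only seed-incident edges (`edges = "star"`). Seed proteins with no PPI
#' edge remain as isolated nodes.
#'
#' @param compound_targets Character vector of compound-target ids.
#' @param disease Target set from [read_disease_targets()].
#' @param ppi Merged, filtered PPI records.
#' @param edges Edge rule, `"induced"` or `"star"`.
#' @param name Network name attribute.
#' @return An undirected igraph with roles COMPOUND_TARGET / DISEASE_TARGET /
#'   SHARED_TARGET / OTHER_PROTEIN.
#' @export
build_ppi_expansion_network <- function(compound_targets, disease, ppi,
                                        edges = c("induced", "star"),
                                        name = "ppi_expansion") {
  edges <- match.arg(edges)
  dt <- disease$target_ids
  seeds <- unique(c(compound_targets, dt))
  if (length(seeds) == 0) stop("empty seed set", call. = FALSE)
  touch_a <- ppi$source_id %in% seeds
  touch_b <- ppi$target_id %in% seeds
  nb <- unique(c(ppi$target_id[touch_a], ppi$source_id[touch_b]))
  nodes <- unique(c(seeds, nb))
  in_set <- ppi$source_id %in% nodes & ppi$target_id %in% nodes
  keep <- if (edges == "induced") in_set else (in_set & (touch_a | touch_b))
  roles <- ifelse(nodes %in% compound_targets & nodes %in% dt, "SHARED_TARGET",
           ifelse(nodes %in% compound_targets, "COMPOUND_TARGET",
           ifelse(nodes %in% dt, "DISEASE_TARGET", "OTHER_PROTEIN")))
  net <- pharm_network(nodes, roles,
                       cbind(ppi$source_id[keep], ppi$target_id[keep]),
                       name)
  tal <- role_tally(net)
  message("build_ppi_expansion_network: ", igraph::vcount(net), " nodes (",
          paste(names(tal), tal, sep = "=", collapse = ", "), "), ",
          igraph::ecount(net), " edges [", edges, "]")
  net
}

#' Induced subnetwork on a node subset
#'
#' Keeps the given nodes and every edge with both endpoints among them.
#' With `drop_isolated = TRUE`, nodes of degree zero *in the subgraph* are
#' removed afterwards — the rule used for the major-node direct-interaction
#' network.
#'
#' @param net A network.
#' @param keep Character vector of node ids to keep (must all be in `net`).
#' @param drop_isolated Remove nodes isolated within the subgraph.
#' @param name Name for the new network; defaults to `<old>_sub`.
#' @return The induced network.
#' @export
induced_subnetwork <- function(net, keep, drop_isolated = FALSE, name = NULL) {
  if (length(keep) == 0) stop("empty keep set", call. = FALSE)
  missing <- setdiff(keep, igraph::V(net)$name)
  if (length(missing) > 0) {
    stop("keep set contains nodes absent from the network: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  sub <- igraph::induced_subgraph(net, vids = keep)
  if (drop_isolated) {
    iso <- igraph::V(sub)[igraph::degree(sub) == 0]
    if (length(iso) > 0) {
      message("induced_subnetwork: dropping ", length(iso),
              " isolated node(s)")
      sub <- igraph::delete_vertices(sub, iso)
    }
  }
  sub$name <- if (is.null(name)) paste0(net$name, "_sub") else name
  sub
}
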