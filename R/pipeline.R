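pipeline_defaults <- function() {
  list(min_score = 0.4,
       ease = TRUE,
       edges = "induced",
       drop_isolated = TRUE,
       closeness = "wf",
       correction = "none",
       background = "table")
}

#' Validate and normalize a pipeline configuration
#'
#' A configuration is a named list (or a YAML/JSON file) with an `inputs`
#' block naming the five tables and optional analysis settings. Defaults:
#' `min_score` 0.4 (strict), EASE p-values, induced expansion edges,
#' isolated-node removal in the major-node subnetwork, Wasserman-Faust
#' closeness, no multiple-testing correction, annotation-table background.
#' Unknown keys and out-of-range values are rejected.
#'
#' @param config Named list, or path to a YAML or JSON file.
#' @return The normalized configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (tolower(tools::file_ext(config)) == "json") {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  known <- c("inputs", names(pipeline_defaults()))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  bad <- character(0)
  if (!is.numeric(cfg$min_score) || cfg$min_score < 0 || cfg$min_score > 1) {
    bad <- c(bad, "min_score (must be in [0,1])")
  }
  if (!is.logical(cfg$ease)) bad <- c(bad, "ease (must be logical)")
  if (!cfg$edges %in% c("induced", "star")) {
    bad <- c(bad, "edges (must be 'induced' or 'star')")
  }
  if (!is.logical(cfg$drop_isolated)) {
    bad <- c(bad, "drop_isolated (must be logical)")
  }
  if (!cfg$closeness %in% c("wf", "raw")) {
    bad <- c(bad, "closeness (must be 'wf' or 'raw')")
  }
  if (!cfg$correction %in% c("none", "BH")) {
    bad <- c(bad, "correction (must be 'none' or 'BH')")
  }
  if (!cfg$background %in% c("table", "network")) {
    bad <- c(bad, "background (must be 'table' or 'network')")
  }
  if (length(bad) > 0) {
    stop("config error: invalid value(s) for: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  if (!is.null(config$inputs)) {
    req <- c("compounds", "compound_interactions", "disease_targets", "ppi")
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss) > 0) {
      stop("config error: inputs missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg
}

#' Run the full network-pharmacology pipeline
#'
#' Ingests the five tables, builds the compound-target, herb-target-disease,
#' and PPI expansion networks, scores the expansion network's topology,
#' selects major nodes and potential targets, builds the major-node
#' direct-interaction network, runs term enrichment on the potential
#' targets, and writes all exports plus a JSON run report to `out_dir`. Any
#' stage failure aborts with the stage name, removing partial outputs.
#'
#' @param config Configuration (list or file path, see [validate_config()]);
#'   `inputs` may name files from [write_fixture()] via [fixture_paths()].
#' @param out_dir Output directory.
#' @return The run report, invisibly (a list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  if (is.null(cfg$inputs)) stop("config error: inputs block required",
                                call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "ingest"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    compounds <- read_compound_table(cfg$inputs$compounds)
    ct_inter <- read_interaction_table(cfg$inputs$compound_interactions,
                                       min_score = cfg$min_score)
    disease <- read_disease_targets(cfg$inputs$disease_targets)
    ppi_tabs <- lapply(cfg$inputs$ppi, read_interaction_table,
                       min_score = cfg$min_score)
    ppi <- merge_ppi_sources(ppi_tabs)
    annotations <- if (!is.null(cfg$inputs$annotations)) {
      read_annotation_table(cfg$inputs$annotations)
    }

    stage <- "netbuild"
    net1 <- build_compound_target_network(compounds, ct_inter)
    net2 <- build_herb_target_disease_network(compounds, ct_inter, disease,
                                              ppi)
    ct_ids <- compound_target_ids(compounds, ct_inter)
    net3 <- build_ppi_expansion_network(ct_ids, disease, ppi,
                                        edges = cfg$edges)

    stage <- "topology"
    topo <- centrality_table(net3, closeness_method = cfg$closeness)

    stage <- "hubsel"
    th <- compute_thresholds(topo)
    major <- select_major_nodes(topo, th)
    roles3 <- node_roles(net3)
    pot <- potential_targets(major,
                             names(roles3)[roles3 == "COMPOUND_TARGET"],
                             names(roles3)[roles3 == "SHARED_TARGET"])
    major_net <- induced_subnetwork(net3, major,
                                    drop_isolated = cfg$drop_isolated,
                                    name = "major_direct_interaction")

    stage <- "enrich"
    enr <- NULL
    if (!is.null(annotations) && length(pot) > 0) {
      bg <- if (cfg$background == "network") {
        intersect(annotations$background, igraph::V(net3)$name)
      }
      enr <- enrich(pot, annotations, background = bg, ease = cfg$ease,
                    correction = cfg$correction)
    }

    stage <- "export"
    nets <- list(compound_target = net1, herb_target_disease = net2,
                 ppi_expansion = net3, major_direct_interaction = major_net)
    for (nm in names(nets)) {
      written <- c(written,
        write_network_graphml(nets[[nm]], file.path(out_dir, paste0(nm, ".graphml"))),
        write_network_sif(nets[[nm]], file.path(out_dir, paste0(nm, ".sif"))),
        write_edge_tsv(nets[[nm]], file.path(out_dir, paste0(nm, "_edges.tsv"))))
    }
    written <- c(written,
      write_centrality_tsv(topo, file.path(out_dir, "centrality.tsv")))
    hubs <- structure(list(thresholds = th, major_nodes = major,
                           potential_targets = pot,
                           table = topo[topo$node %in% major, , drop = FALSE],
                           source_network = net3$name),
                      class = "hub_selection")
    write_hub_report(hubs, file.path(out_dir, "hub_selection.json"),
                     file.path(out_dir, "major_nodes.tsv"))
    written <- c(written, file.path(out_dir, "hub_selection.json"),
                 file.path(out_dir, "major_nodes.tsv"))
    if (!is.null(enr)) {
      written <- c(written,
        write_enrichment_tsv(enr, file.path(out_dir, "enrichment.tsv")))
    }

    stage <- "report"
    net_summary <- lapply(nets, function(g) {
      list(nodes = igraph::vcount(g), edges = igraph::ecount(g),
           roles = as.list(role_tally(g)))
    })
    report <- list(
      tool = "pharmnet",
      version = as.character(utils::packageVersion("pharmnet")),
      config = cfg[setdiff(names(cfg), "inputs")],
      counts = list(
        compound_records = nrow(compounds),
        distinct_compounds = length(unique(compounds$compound_id)),
        compounds_with_targets = sum(unique(compounds$compound_id) %in%
                                       ct_inter$source_id),
        compound_targets = length(ct_ids),
        disease_targets = length(disease$target_ids),
        ppi_edges = nrow(ppi)),
      networks = net_summary,
      thresholds = as.list(th),
      n_major = length(major),
      n_potential_targets = length(pot),
      potential_targets = pot,
      top_enrichment = if (!is.null(enr)) {
        utils::head(enr[, c("term_id", "term_name", "k", "K", "fold", "p")], 5)
      },
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, file.path(out_dir, "report.json"))
    invisible(report)
  }, error = on_fail)
}

#' Strip volatile fields from a run report
#'
#' Utility for determinism checks: returns the report with the timestamp
#' removed, so two runs on identical inputs compare equal.
#'
#' @param report A run report (list, or path to `report.json`).
#' @return The report list without its `timestamp` field.
#' @export
report_fingerprint <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  }
  report$timestamp <- NULL
  report
}
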