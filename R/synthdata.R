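#' Synthetic-study configuration
#'
#' Describes one complete synthetic network-pharmacology study: the
#' herb-compound roster, the chemical-protein interaction structure, the
#' disease-target list and its overlap with compound targets, a
#' core-periphery PPI background with planted hub proteins, and an
#' annotation table with planted enriched terms. All marginal counts are
#' enforced exactly by construction; the randomness is in which identifiers
#' play which part and in the confidence scores.
#'
#' The PPI background is a planted core-periphery graph: `planted_hubs`
#' proteins form a densely connected core (pairwise edge probability
#' `ppi_model$p_core`), each core protein additionally receives a quota of
#' dedicated low-degree attachment proteins, and the remaining
#' first-neighbor proteins attach preferentially to the core with propensity
#' multiplier `hub_boost`. Every non-core node's degree inside the expansion
#' network is capped at `ppi_model$periph_cap`, so the degree distribution
#' is heavy-tailed and the core is the natural hub set.
#'
#' @param n_herbs Number of herbs in the formula.
#' @param compounds_per_herb Integer vector (length `n_herbs`) of
#'   herb-compound records per herb.
#' @param share_prob Probability that a compound record reuses a compound
#'   already listed under an earlier herb (formulas share constituents).
#' @param frac_compounds_with_targets Fraction of distinct compounds given
#'   at least one above-threshold chemical-protein interaction.
#' @param n_targets Number of distinct compound-target proteins.
#' @param ct_edge_factor Target ratio of compound-target edges to targets
#'   (target popularity follows preferential attachment beyond coverage).
#' @param n_disease_targets Disease-target list size.
#' @param n_shared Disease targets that are also compound targets.
#' @param n_disease_linked Exclusive disease targets given a PPI edge to a
#'   compound target (the rest stay unlinked).
#' @param n_neighbors First-neighbor proteins of the seed set in the PPI
#'   background (exactly; each is guaranteed one seed-incident edge).
#' @param ppi_model List: `model` ("core_periphery" or "er"), `p_core`
#'   (core pairwise edge probability), `nn_factor` (neighbor-neighbor edges
#'   per neighbor), `periph_cap` (max non-core degree in the expansion
#'   network), `n_far` (background proteins not adjacent to any seed).
#' @param planted_hubs Size of the planted core (0 disables planting).
#' @param hub_roles Named vector `c(ct=, shared=, neighbor=)` splitting the
#'   core over exclusive compound targets, shared targets, and neighbor
#'   proteins; `NULL` derives a default split.
#' @param hub_boost Attachment-propensity multiplier of core over periphery.
#' @param pendant_quota Dedicated degree-1 attachment proteins per
#'   seed-core hub.
#' @param bhub_quota Dedicated degree-2 attachment proteins per
#'   neighbor-core hub (one edge to the hub, one to a seed hub).
#' @param planted_terms Number of planted enriched annotation terms.
#' @param term_enrichment Probability that each planted-hub compound target
#'   is annotated to a planted term.
#' @param term_size Gene-set size of each planted term.
#' @param n_terms Total number of annotation terms.
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @return A validated list of class `study_config`.
#' @export
study_config <- function(n_herbs = 4,
                         compounds_per_herb = c(8, 10, 12, 14),
                         share_prob = 0.05,
                         frac_compounds_with_targets = 0.25,
                         n_targets = 40,
                         ct_edge_factor = 1.8,
                         n_disease_targets = 12,
                         n_shared = 4,
                         n_disease_linked = 6,
                         n_neighbors = 150,
                         ppi_model = list(model = "core_periphery",
                                          p_core = 0.5, nn_factor = 0.6,
                                          periph_cap = 3, n_far = 30),
                         planted_hubs = 20,
                         hub_roles = NULL,
                         hub_boost = 8,
                         pendant_quota = 3,
                         bhub_quota = 4,
                         planted_terms = 1,
                         term_enrichment = 0.85,
                         term_size = 20,
                         n_terms = 25,
                         seed = 1) {
  cfg <- list(n_herbs = as.integer(n_herbs),
              compounds_per_herb = as.integer(compounds_per_herb),
              share_prob = share_prob,
              frac_compounds_with_targets = frac_compounds_with_targets,
              n_targets = as.integer(n_targets),
              ct_edge_factor = ct_edge_factor,
              n_disease_targets = as.integer(n_disease_targets),
              n_shared = as.integer(n_shared),
              n_disease_linked = as.integer(n_disease_linked),
              n_neighbors = as.integer(n_neighbors),
              ppi_model = utils::modifyList(
                list(model = "core_periphery", p_core = 0.5, nn_factor = 0.6,
                     periph_cap = 3, n_far = 20),
                as.list(ppi_model)),
              planted_hubs = as.integer(planted_hubs),
              hub_roles = hub_roles,
              hub_boost = hub_boost,
              pendant_quota = as.integer(pendant_quota),
              bhub_quota = as.integer(bhub_quota),
              planted_terms = as.integer(planted_terms),
              term_enrichment = term_enrichment,
              term_size = as.integer(term_size),
              n_terms = as.integer(n_terms),
              seed = as.integer(seed))
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  err <- function(...) stop("config error: ", ..., call. = FALSE)
  if (length(cfg$compounds_per_herb) != cfg$n_herbs) {
    err("compounds_per_herb must have length n_herbs")
  }
  if (any(cfg$compounds_per_herb < 1)) err("compounds_per_herb must be >= 1")
  if (cfg$share_prob < 0 || cfg$share_prob >= 1) err("share_prob in [0,1)")
  total <- sum(cfg$compounds_per_herb)
  if (cfg$frac_compounds_with_targets <= 0 ||
      cfg$frac_compounds_with_targets > 1) {
    err("frac_compounds_with_targets in (0,1]")
  }
  if (round(cfg$frac_compounds_with_targets * total) < 1) {
    err("frac_compounds_with_targets leaves no compound with targets")
  }
  if (cfg$n_targets < 1) err("n_targets >= 1")
  if (cfg$n_shared > min(cfg$n_targets, cfg$n_disease_targets)) {
    err("n_shared exceeds min(n_targets, n_disease_targets)")
  }
  if (cfg$n_disease_linked > cfg$n_disease_targets - cfg$n_shared) {
    err("n_disease_linked exceeds the exclusive disease-target count")
  }
  pm <- cfg$ppi_model
  if (!pm$model %in% c("core_periphery", "er")) {
    err("ppi_model$model must be 'core_periphery' or 'er'")
  }
  if (pm$p_core < 0 || pm$p_core > 1) err("ppi_model$p_core in [0,1]")
  if (pm$periph_cap < 2) err("ppi_model$periph_cap >= 2")
  if (cfg$planted_hubs > 0 && pm$model == "core_periphery") {
    hr <- cfg$hub_roles
    if (is.null(hr)) {
      # ~3/4 of the core are compound/shared targets, as in a scaled-down
      # study where most hubs are drug targets
      sh <- min(cfg$n_shared, max(0L, round(cfg$planted_hubs * 0.2)))
      ct <- min(cfg$n_targets - cfg$n_shared, round(cfg$planted_hubs * 0.55))
      hr <- c(ct = ct, shared = sh, neighbor = cfg$planted_hubs - ct - sh)
    }
    hr <- unlist(hr)[c("ct", "shared", "neighbor")]
    if (any(is.na(hr)) || sum(hr) != cfg$planted_hubs) {
      err("hub_roles must be c(ct=, shared=, neighbor=) summing to planted_hubs")
    }
    if (hr[["ct"]] > cfg$n_targets - cfg$n_shared) err("too many ct hubs")
    if (hr[["shared"]] > cfg$n_shared) err("too many shared hubs")
    consumed <- (hr[["ct"]] + hr[["shared"]]) * cfg$pendant_quota +
      hr[["neighbor"]] * cfg$bhub_quota
    if (hr[["neighbor"]] + consumed > cfg$n_neighbors) {
      err("n_neighbors too small for hub quotas")
    }
    cfg$hub_roles <- hr
  }
  if (cfg$term_enrichment < 0 || cfg$term_enrichment > 1) {
    err("term_enrichment in [0,1]")
  }
  if (cfg$planted_terms > cfg$n_terms) err("planted_terms > n_terms")
  structure(cfg, class = "study_config")
}

#' Paper-scale study configuration
#'
#' The fixed study conditions used throughout: 435 herb-compound records
#' over four herbs (32/88/143/172), 34 compounds with above-threshold
#' interactions covering 122 targets, 24 disease targets of which 7 are
#' shared with the compound targets and 11 of the exclusive ones have a PPI
#' link to a compound target, and a PPI background whose first-neighbor
#' expansion of the seed set yields exactly 470 additional proteins (609
#' nodes in total) around a planted 41-node core (16 exclusive compound
#' targets, 4 shared targets, 21 neighbor proteins).
#'
#' @param seed Integer RNG seed.
#' @return A `study_config`.
#' @export
paper_scale_config <- function(seed = 1) {
  study_config(n_herbs = 4,
               compounds_per_herb = c(32, 88, 143, 172),
               share_prob = 0,
               frac_compounds_with_targets = 34 / 435,
               n_targets = 122,
               ct_edge_factor = 1.8,
               n_disease_targets = 24,
               n_shared = 7,
               n_disease_linked = 11,
               n_neighbors = 470,
               ppi_model = list(model = "core_periphery", p_core = 0.35,
                                nn_factor = 0.6, periph_cap = 3, n_far = 60),
               planted_hubs = 41,
               hub_roles = c(ct = 16, shared = 4, neighbor = 21),
               hub_boost = 8,
               pendant_quota = 4,
               bhub_quota = 6,
               planted_terms = 1,
               term_enrichment = 0.8,
               term_size = 25,
               n_terms = 30,
               seed = seed)
}

with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# sample() that never interprets a length-1 x as 1:x
sample_ids <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Generate a synthetic study
#'
#' Produces the five table kinds the pipeline consumes (herb-compound
#' roster, compound-target interactions in the integer 0-1000 score dialect,
#' disease-target list, two scored PPI edge lists, GMT annotation table)
#' plus the planted ground truth. Structural records receive confidence
#' scores strictly above 0.4; decoy records (scores in \[0.2, 0.4\]) are mixed
#' in so the score filter is exercised without disturbing the post-filter
#' marginals, which match the configuration exactly.
#'
#' @param cfg A `study_config`.
#' @return A list of class `study_bundle` with elements `config`, `tables`
#'   (`compounds`, `compound_interactions`, `disease_targets`, `ppi` (list
#'   of two data.frames), `annotations`), and `truth` (planted hubs, planted
#'   target set, planted term ids, neighbor/far rosters).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  with_rng_seed(cfg$seed, generate_study_impl(cfg))
}

generate_study_impl <- function(cfg) {
  pm <- cfg$ppi_model

  ## herb-compound roster -------------------------------------------------
  herbs <- paste0("H", seq_len(cfg$n_herbs))
  total_rows <- sum(cfg$compounds_per_herb)
  comp_pool <- sprintf("C%03d", seq_len(total_rows))
  rows <- list()
  used <- character(0)
  next_id <- 1L
  for (i in seq_len(cfg$n_herbs)) {
    ids <- character(cfg$compounds_per_herb[i])
    herb_set <- character(0)
    for (j in seq_len(cfg$compounds_per_herb[i])) {
      reusable <- setdiff(used, herb_set)
      if (length(reusable) > 0 && stats::runif(1) < cfg$share_prob) {
        id <- sample_ids(reusable, 1)
      } else {
        id <- comp_pool[next_id]
        next_id <- next_id + 1L
        used <- c(used, id)
      }
      ids[j] <- id
      herb_set <- c(herb_set, id)
    }
    rows[[i]] <- data.frame(herb_id = herbs[i], compound_id = ids,
                            compound_name = ids, stringsAsFactors = FALSE)
  }
  compounds <- do.call(rbind, rows)

  ## compound-target interactions (integer score dialect) -----------------
  distinct <- unique(compounds$compound_id)
  n_with <- round(cfg$frac_compounds_with_targets * length(distinct))
  sel <- sort(sample_ids(distinct, n_with))
  tids <- sprintf("T%03d", seq_len(cfg$n_targets))
  ct_from <- character(0); ct_to <- character(0)
  perm_t <- sample_ids(tids, length(tids))
  perm_c <- sample_ids(sel, length(sel))
  if (cfg$n_targets >= n_with) {
    ct_from <- perm_c
    ct_to <- perm_t[seq_len(n_with)]
    rest <- perm_t[-seq_len(n_with)]
    if (length(rest) > 0) {
      ct_from <- c(ct_from, sample_ids(sel, length(rest), replace = TRUE))
      ct_to <- c(ct_to, rest)
    }
  } else {
    ct_to <- rep(perm_t, length.out = n_with)
    ct_from <- perm_c
  }
  ct_key <- paste(ct_from, ct_to)
  t_deg <- table(factor(ct_to, levels = tids))
  n_goal <- max(length(ct_from), round(cfg$ct_edge_factor * cfg$n_targets))
  tries <- 0L
  while (length(ct_from) < n_goal && tries < 50L * n_goal) {
    tries <- tries + 1L
    cp <- sample_ids(sel, 1)
    tg <- sample_ids(tids, 1, prob = as.numeric(t_deg) + 1)
    k <- paste(cp, tg)
    if (k %in% ct_key) next
    ct_from <- c(ct_from, cp); ct_to <- c(ct_to, tg)
    ct_key <- c(ct_key, k)
    t_deg[tg] <- t_deg[tg] + 1
  }
  ct <- data.frame(chemical = ct_from, protein = ct_to,
                   score = sample(401:999, length(ct_from), replace = TRUE),
                   stringsAsFactors = FALSE)
  # decoy rows: compounds without retained evidence, scores <= 400
  unsel <- setdiff(distinct, sel)
  n_dec <- length(unsel)
  if (n_dec > 0) {
    dec <- data.frame(chemical = unsel,
                      protein = sample_ids(tids, n_dec, replace = TRUE),
                      score = sample(150:400, n_dec, replace = TRUE),
                      stringsAsFactors = FALSE)
    ct <- rbind(ct, dec)
  }
  ct <- ct[sample.int(nrow(ct)), , drop = FALSE]
  rownames(ct) <- NULL

  ## disease targets ------------------------------------------------------
  shared <- sort(sample_ids(tids, cfg$n_shared))
  n_excl <- cfg$n_disease_targets - cfg$n_shared
  dids <- sprintf("D%02d", seq_len(n_excl))
  linked <- sort(sample_ids(dids, cfg$n_disease_linked))
  disease_ids <- sample_ids(c(shared, dids), cfg$n_disease_targets)

  ## PPI background -------------------------------------------------------
  seeds <- c(tids, dids)
  nb <- sprintf("B%03d", seq_len(cfg$n_neighbors))
  far <- if (pm$n_far > 0) sprintf("F%03d", seq_len(pm$n_far)) else character(0)

  deg3 <- setNames(integer(length(seeds) + length(nb)), c(seeds, nb))
  efrom <- character(0); eto <- character(0)
  ekeys <- new.env(hash = TRUE, parent = emptyenv())
  add_edge <- function(a, b, count = TRUE) {
    if (a == b) return(FALSE)
    k <- unordered_key(a, b)
    if (!is.null(ekeys[[k]])) return(FALSE)
    ekeys[[k]] <- TRUE
    efrom <<- c(efrom, a); eto <<- c(eto, b)
    if (count) {
      if (a %in% names(deg3)) deg3[a] <<- deg3[a] + 1L
      if (b %in% names(deg3)) deg3[b] <<- deg3[b] + 1L
    }
    TRUE
  }

  truth_hubs <- character(0)
  hub_ct <- hub_sh <- hub_nb <- character(0)
  if (pm$model == "core_periphery" && cfg$planted_hubs > 0) {
    hr <- cfg$hub_roles
    hub_ct <- sort(sample_ids(setdiff(tids, shared), hr[["ct"]]))
    hub_sh <- sort(sample_ids(shared, hr[["shared"]]))
    hub_nb <- nb[seq_len(hr[["neighbor"]])]
    core <- c(hub_ct, hub_sh, hub_nb)
    truth_hubs <- core
    seed_hubs <- c(hub_ct, hub_sh)
    k <- length(core)
    # connectivity ring + dense core
    for (i in seq_len(k)) add_edge(core[i], core[i %% k + 1L])
    if (k >= 2) {
      prs <- utils::combn(core, 2)
      for (j in seq_len(ncol(prs))) {
        if (stats::runif(1) < pm$p_core) add_edge(prs[1, j], prs[2, j])
      }
    }
    # every neighbor-core hub is guaranteed a seed-incident edge
    for (h in hub_nb) add_edge(h, sample_ids(seed_hubs, 1))
    # dedicated attachments: degree-1 pendants on seed hubs, degree-2 on
    # neighbor hubs (second edge to a seed hub keeps them seed-adjacent)
    pool <- setdiff(nb, hub_nb)
    ptr <- 0L
    pendants <- character(0)
    for (h in seed_hubs) {
      for (q in seq_len(cfg$pendant_quota)) {
        ptr <- ptr + 1L; p <- pool[ptr]
        add_edge(p, h); pendants <- c(pendants, p)
      }
    }
    for (h in hub_nb) {
      for (q in seq_len(cfg$bhub_quota)) {
        ptr <- ptr + 1L; p <- pool[ptr]
        add_edge(p, h); add_edge(p, sample_ids(seed_hubs, 1))
        pendants <- c(pendants, p)
      }
    }
    free_nb <- if (ptr > 0) pool[-seq_len(ptr)] else pool
  } else {
    core <- seed_hubs <- pendants <- character(0)
    free_nb <- nb
  }

  # linked exclusive disease targets: one PPI edge to a compound target
  ct_pool <- if (length(c(hub_ct, hub_sh)) > 0) c(hub_ct, hub_sh) else tids
  for (d in linked) add_edge(d, sample_ids(ct_pool, 1))

  # remaining neighbors: first edge to a seed (core-boosted), optional second
  cap <- if (pm$model == "er") .Machine$integer.max else pm$periph_cap
  attach_target <- function() {
    cand <- c(core, seeds[!(seeds %in% core) & deg3[seeds] < cap])
    if (length(cand) == 0) cand <- seeds
    w <- if (length(core) == 0) rep(1, length(cand)) else {
      ifelse(cand %in% core, cfg$hub_boost * (deg3[cand] + 1),
             deg3[cand] + 1)
    }
    sample_ids(cand, 1, prob = w)
  }
  seed_first <- function() {
    # first edge must touch a seed so the node is in the expansion network
    cand <- c(seed_hubs, seeds[!(seeds %in% core) & deg3[seeds] < cap])
    if (length(cand) == 0) cand <- seeds
    w <- if (length(core) == 0) rep(1, length(cand)) else {
      ifelse(cand %in% core, cfg$hub_boost * (deg3[cand] + 1),
             deg3[cand] + 1)
    }
    sample_ids(cand, 1, prob = w)
  }
  for (b in free_nb) {
    add_edge(b, seed_first())
    if (stats::runif(1) < 0.4 && deg3[b] < cap) {
      tgt <- attach_target()
      if (tgt != b) add_edge(b, tgt)
    }
  }
  # neighbor-neighbor edges up to the periphery cap
  n_nn <- round(pm$nn_factor * cfg$n_neighbors)
  tries <- 0L
  added <- 0L
  while (added < n_nn && tries < 50L * max(n_nn, 1L)) {
    tries <- tries + 1L
    open <- free_nb[deg3[free_nb] < cap]
    if (length(open) < 2) break
    pr <- sample_ids(open, 2)
    if (add_edge(pr[1], pr[2])) added <- added + 1L
  }
  # far proteins: attached to neighbors/far only, never to a seed
  for (f in far) {
    n_att <- sample(1:2, 1)
    for (q in seq_len(n_att)) {
      other <- sample_ids(c(free_nb, setdiff(far, f)), 1)
      add_edge(f, other, count = FALSE)
    }
  }

  n_struct <- length(efrom)
  ppi <- data.frame(source_id = efrom, target_id = eto,
                    score = round(stats::runif(n_struct, 0.401, 0.999), 3),
                    stringsAsFactors = FALSE)
  # decoys below the filter: random pairs over all PPI proteins
  allp <- c(seeds, nb, far)
  n_dec <- round(0.15 * n_struct)
  if (n_dec > 0) {
    a <- sample_ids(allp, n_dec, replace = TRUE)
    b <- sample_ids(allp, n_dec, replace = TRUE)
    ok <- a != b
    dec <- data.frame(source_id = a[ok], target_id = b[ok],
                      score = round(stats::runif(sum(ok), 0.2, 0.4), 3),
                      stringsAsFactors = FALSE)
    ppi <- rbind(ppi, dec)
  }
  # a couple of self-loops to exercise the self-loop filter
  sl <- sample_ids(allp, 2)
  ppi <- rbind(ppi, data.frame(source_id = sl, target_id = sl,
                               score = c(0.9, 0.75), stringsAsFactors = FALSE))
  # split over two source tables with a small overlap (lower duplicate score)
  src <- sample(c(1L, 2L), nrow(ppi), replace = TRUE)
  dup_idx <- which(seq_len(nrow(ppi)) <= n_struct & stats::runif(nrow(ppi)) < 0.1)
  dup <- ppi[dup_idx, , drop = FALSE]
  if (nrow(dup) > 0) {
    dup$score <- pmax(0.401, round(dup$score - stats::runif(nrow(dup), 0, 0.05), 3))
  }
  ppi_a <- rbind(ppi[src == 1L, , drop = FALSE],
                 dup[src[dup_idx] == 2L, , drop = FALSE])
  ppi_b <- rbind(ppi[src == 2L, , drop = FALSE],
                 dup[src[dup_idx] == 1L, , drop = FALSE])
  ppi_a <- ppi_a[sample.int(nrow(ppi_a)), , drop = FALSE]
  ppi_b <- ppi_b[sample.int(nrow(ppi_b)), , drop = FALSE]
  rownames(ppi_a) <- rownames(ppi_b) <- NULL

  ## annotation table with planted enriched terms -------------------------
  background <- sort(allp)
  truth_targets <- c(hub_ct, hub_sh)     # expected potential-target set
  terms <- list()
  planted_ids <- character(0)
  for (i in seq_len(cfg$n_terms)) {
    id <- sprintf("GO:%07d", i)
    if (i <= cfg$planted_terms && length(truth_targets) > 0) {
      hits <- truth_targets[stats::runif(length(truth_targets)) <
                              cfg$term_enrichment]
      filler <- sample_ids(setdiff(background, truth_targets),
                           max(0, cfg$term_size - length(hits)))
      genes <- sort(c(hits, filler))
      name <- sprintf("planted process %03d", i)
      planted_ids <- c(planted_ids, id)
    } else {
      genes <- sort(sample_ids(background, sample(10:40, 1)))
      name <- sprintf("synthetic process %03d", i)
    }
    terms[[id]] <- list(term_name = name, genes = genes)
  }
  annotations <- structure(list(terms = terms, background = background),
                           class = "annotation_table")

  structure(list(
    config = cfg,
    tables = list(compounds = compounds,
                  compound_interactions = ct,
                  disease_targets = disease_ids,
                  ppi = list(ppi_source_a = ppi_a, ppi_source_b = ppi_b),
                  annotations = annotations),
    truth = list(planted_hubs = truth_hubs,
                 hub_ct = hub_ct, hub_shared = hub_sh, hub_neighbor = hub_nb,
                 planted_targets = truth_targets,
                 planted_terms = planted_ids,
                 selected_compounds = sel,
                 shared_targets = shared,
                 linked_disease = linked,
                 neighbors = nb, far = far)),
    class = "study_bundle")
}

#' Write a study bundle as a fixture directory
#'
#' Writes the five input tables (TSV/GMT) plus a JSON manifest recording the
#' configuration, so the bundle can be regenerated byte-identically.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- bundle$tables
  paths <- list(
    compounds = file.path(dir, "compounds.tsv"),
    compound_interactions = file.path(dir, "compound_interactions.tsv"),
    disease_targets = file.path(dir, "disease_targets.tsv"),
    ppi_source_a = file.path(dir, "ppi_source_a.tsv"),
    ppi_source_b = file.path(dir, "ppi_source_b.tsv"),
    annotations = file.path(dir, "annotations.gmt"),
    manifest = file.path(dir, "manifest.json"))
  wt <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  }
  wt(tb$compounds, paths$compounds)
  wt(tb$compound_interactions, paths$compound_interactions)
  writeLines(c("target_id", tb$disease_targets), paths$disease_targets)
  fmt_ppi <- function(df) {
    data.frame(source_id = df$source_id, target_id = df$target_id,
               score = sprintf("%.3f", df$score), stringsAsFactors = FALSE)
  }
  wt(fmt_ppi(tb$ppi$ppi_source_a), paths$ppi_source_a)
  wt(fmt_ppi(tb$ppi$ppi_source_b), paths$ppi_source_b)
  gmt <- vapply(names(tb$annotations$terms), function(id) {
    tm <- tb$annotations$terms[[id]]
    paste(c(id, tm$term_name, tm$genes), collapse = "\t")
  }, character(1))
  writeLines(unname(gmt), paths$annotations)
  cfg_out <- unclass(bundle$config)
  if (!is.null(cfg_out$hub_roles)) {
    cfg_out$hub_roles <- as.list(cfg_out$hub_roles)  # keep names in JSON
  }
  manifest <- list(generator = "pharmnet::generate_study",
                   version = as.character(utils::packageVersion("pharmnet")),
                   seed = bundle$config$seed,
                   config = cfg_out)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Rebuild a study configuration from a fixture manifest
#'
#' @param path Path to a `manifest.json` written by [write_fixture()].
#' @return A `study_config` equal to the one that produced the fixture.
#' @export
study_config_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  cfg$hub_roles <- if (!is.null(cfg$hub_roles)) unlist(cfg$hub_roles)
  cfg$ppi_model <- as.list(cfg$ppi_model)
  do.call(study_config, cfg)
}

#' Fixture file paths in a directory
#'
#' @param dir Directory written by [write_fixture()].
#' @return Named list of the standard fixture file paths.
#' @export
fixture_paths <- function(dir) {
  list(compounds = file.path(dir, "compounds.tsv"),
       compound_interactions = file.path(dir, "compound_interactions.tsv"),
       disease_targets = file.path(dir, "disease_targets.tsv"),
       ppi = c(file.path(dir, "ppi_source_a.tsv"),
               file.path(dir, "ppi_source_b.tsv")),
       annotations = file.path(dir, "annotations.gmt"),
       manifest = file.path(dir, "manifest.json"))
}
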