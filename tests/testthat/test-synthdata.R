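test_that("generation is deterministic under a fixed seed", {
  b1 <- suppressMessages(generate_study(study_config(seed = 7)))
  b2 <- suppressMessages(generate_study(study_config(seed = 7)))
  expect_identical(b1$tables, b2$tables)
  expect_identical(b1$truth, b2$truth)

  d1 <- tempfile(); d2 <- tempfile()
  suppressMessages(write_fixture(b1, d1))
  suppressMessages(write_fixture(b2, d2))
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  b3 <- suppressMessages(generate_study(study_config(seed = 8)))
  expect_false(identical(b1$tables, b3$tables))
})

test_that("generated marginals match the configuration exactly", {
  cfg <- study_config(seed = 3)
  b <- suppressMessages(generate_study(cfg))
  tb <- b$tables
  expect_equal(unname(table(tb$compounds$herb_id)),
               cfg$compounds_per_herb, ignore_attr = TRUE)
  expect_length(tb$disease_targets, cfg$n_disease_targets)
  expect_length(b$truth$shared_targets, cfg$n_shared)
  expect_length(b$truth$linked_disease, cfg$n_disease_linked)
  expect_length(b$truth$planted_hubs, cfg$planted_hubs)
  n_with <- round(cfg$frac_compounds_with_targets *
                    length(unique(tb$compounds$compound_id)))
  expect_length(b$truth$selected_compounds, n_with)
  # after the score filter, kept interactions cover exactly the configured
  # compounds and targets
  kept <- tb$compound_interactions[tb$compound_interactions$score > 400, ]
  expect_setequal(unique(kept$chemical), b$truth$selected_compounds)
  expect_length(unique(kept$protein), cfg$n_targets)
})

test_that("infeasible configurations are rejected", {
  expect_error(study_config(n_shared = 50), "n_shared")
  expect_error(study_config(n_disease_linked = 50), "n_disease_linked")
  expect_error(study_config(compounds_per_herb = c(5, 5)), "length")
  expect_error(study_config(hub_roles = c(ct = 1, shared = 1, neighbor = 1)),
               "hub_roles")
  expect_error(study_config(n_neighbors = 10), "n_neighbors")
  expect_error(study_config(frac_compounds_with_targets = 0), "frac")
})

test_that("planted_hubs = 0 disables planting but still yields a study", {
  b <- suppressMessages(generate_study(study_config(planted_hubs = 0,
                                                    seed = 5)))
  expect_length(b$truth$planted_hubs, 0)
  expect_gt(nrow(b$tables$ppi$ppi_source_a), 0)
})

test_that("PPI degree distribution is heavy-tailed under the default model", {
  b <- suppressMessages(generate_study(study_config(seed = 9)))
  ppi <- suppressMessages(merge_ppi_sources(lapply(b$tables$ppi, function(p) {
    p$origin <- "syn"
    p[p$score > 0.4, ]
  })))
  deg <- table(c(ppi$source_id, ppi$target_id))
  expect_gte(max(deg), 5 * stats::median(deg))
})

test_that("planted-term fold enrichment matches its expectation over seeds", {
  folds <- numeric(20)
  expected <- NULL
  for (i in seq_len(20)) {
    b <- suppressMessages(generate_study(study_config(seed = 200 + i)))
    ann <- b$tables$annotations
    study <- b$truth$planted_targets
    res <- suppressWarnings(enrich(study, ann, ease = FALSE))
    row <- res[res$term_id == b$truth$planted_terms[1], ]
    folds[i] <- row$fold
    expected <- b$config$term_enrichment * length(ann$background) /
      b$config$term_size
  }
  se <- stats::sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - expected), 3 * se + 1e-9)
})

test_that("fixtures round-trip through the ingest readers", {
  b <- suppressMessages(generate_study(study_config(seed = 13)))
  d <- tempfile()
  suppressMessages(write_fixture(b, d))
  p <- fixture_paths(d)
  comp <- suppressMessages(read_compound_table(p$compounds))
  expect_equal(comp$compound_id, b$tables$compounds$compound_id)
  dis <- suppressMessages(read_disease_targets(p$disease_targets))
  expect_setequal(dis$target_ids, b$tables$disease_targets)
  ann <- suppressMessages(read_annotation_table(p$annotations))
  expect_equal(lapply(ann$terms, `[[`, "genes"),
               lapply(b$tables$annotations$terms, `[[`, "genes"))
})

test_that("manifest records the seed and regenerates byte-identically", {
  b <- suppressMessages(generate_study(study_config(seed = 17)))
  d <- tempfile()
  suppressMessages(write_fixture(b, d))
  man <- jsonlite::read_json(file.path(d, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 17)
  cfg2 <- study_config_from_manifest(file.path(d, "manifest.json"))
  b2 <- suppressMessages(generate_study(cfg2))
  d2 <- tempfile()
  suppressMessages(write_fixture(b2, d2))
  for (f in setdiff(list.files(d), "manifest.json")) {
    expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("the Erdos-Renyi alternative produces a flatter degree spread", {
  cfg <- study_config(ppi_model = list(model = "er"), planted_hubs = 0,
                      seed = 19)
  b <- suppressMessages(generate_study(cfg))
  ppi <- suppressMessages(merge_ppi_sources(lapply(b$tables$ppi, function(p) {
    p$origin <- "syn"
    p[p$score > 0.4, ]
  })))
  deg <- table(c(ppi$source_id, ppi$target_id))
  b2 <- suppressMessages(generate_study(study_config(seed = 19)))
  ppi2 <- suppressMessages(merge_ppi_sources(lapply(b2$tables$ppi, function(p) {
    p$origin <- "syn"
    p[p$score > 0.4, ]
  })))
  deg2 <- table(c(ppi2$source_id, ppi2$target_id))
  expect_lt(max(deg) / stats::median(deg), max(deg2) / stats::median(deg2))
})
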