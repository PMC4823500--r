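test_that("compound table reading counts per-herb rosters correctly", {
  b <- paper_bundle()
  d <- paper_fixture_dir()
  df <- suppressMessages(read_compound_table(file.path(d, "compounds.tsv")))
  expect_equal(nrow(df), 435)
  expect_equal(unname(table(df$herb_id)[paste0("H", 1:4)]),
               as.integer(c(32, 88, 143, 172)), ignore_attr = TRUE)

  one <- write_tsv_lines(c("herb_id\tcompound_id", "H1\tC1"))
  expect_equal(nrow(suppressMessages(read_compound_table(one))), 1)

  dup <- write_tsv_lines(c("herb_id\tcompound_id", "H1\tC1", "H1\tC1"))
  expect_warning(res <- suppressMessages(read_compound_table(dup)),
                 "duplicate")
  expect_equal(nrow(res), 1)
})

test_that("compound table schema and empty-file errors are raised", {
  bad <- write_tsv_lines(c("herb\tcompound", "H1\tC1"))
  expect_error(read_compound_table(bad), "missing column")
  empty <- write_tsv_lines("herb_id\tcompound_id")
  expect_error(suppressMessages(read_compound_table(empty)), "empty")
})

test_that("score filter is strict and the integer dialect divides by 1000", {
  f <- write_tsv_lines(c("source_id\ttarget_id\tscore",
                         "A\tB\t0.39", "A\tC\t0.40", "A\tD\t0.41"))
  rec <- suppressMessages(read_interaction_table(f, min_score = 0.4))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$target_id, "D")

  g <- write_tsv_lines(c("chemical\tprotein\tscore",
                         "C1\tP1\t700", "C1\tP2\t400", "C2\tP1\t999"))
  rec <- suppressMessages(read_interaction_table(g, min_score = 0.4))
  expect_equal(sort(rec$score), c(0.700, 0.999))
})

test_that("self-loops drop and duplicate unordered pairs keep the max score", {
  f <- write_tsv_lines(c("source_id\ttarget_id\tscore",
                         "A\tA\t0.9", "A\tB\t0.5", "B\tA\t0.9"))
  rec <- suppressMessages(read_interaction_table(f))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$score, 0.9)
  expect_setequal(c(rec$source_id, rec$target_id), c("A", "B"))
})

test_that("interaction reader flags unparseable scores and all-filtered files", {
  f <- write_tsv_lines(c("source_id\ttarget_id\tscore",
                         "A\tB\t0.8", "A\tC\tn/a"))
  expect_error(suppressMessages(read_interaction_table(f)),
               "unparseable score.*row")
  g <- write_tsv_lines(c("source_id\ttarget_id\tscore", "A\tB\t0.1"))
  expect_warning(rec <- suppressMessages(read_interaction_table(g)),
                 "filtered")
  expect_equal(nrow(rec), 0)
})

test_that("score filtering is idempotent", {
  d <- paper_fixture_dir()
  rec <- suppressMessages(read_interaction_table(
    file.path(d, "ppi_source_a.tsv"), min_score = 0.4))
  f2 <- tempfile(fileext = ".tsv")
  write.table(rec[, c("source_id", "target_id", "score")], f2, sep = "\t",
              quote = FALSE, row.names = FALSE)
  rec2 <- suppressMessages(read_interaction_table(f2, min_score = 0.4))
  expect_equal(rec2[, c("source_id", "target_id", "score")],
               rec[, c("source_id", "target_id", "score")])
})

test_that("disease-target lists deduplicate and count correctly", {
  d <- paper_fixture_dir()
  ts <- suppressMessages(read_disease_targets(
    file.path(d, "disease_targets.tsv")))
  expect_length(ts$target_ids, 24)

  f <- write_tsv_lines(c("P1", "P1", "P2"))
  expect_length(suppressMessages(read_disease_targets(f))$target_ids, 2)
  g <- write_tsv_lines("P9")
  expect_length(suppressMessages(read_disease_targets(g))$target_ids, 1)
  empty <- tempfile(); file.create(empty)
  expect_error(read_disease_targets(empty), "empty")
})

test_that("PPI source merging unions unordered pairs keeping max score", {
  t1 <- data.frame(source_id = c("A", "C"), target_id = c("B", "D"),
                   score = c(0.5, 0.6), origin = "s1")
  t2 <- data.frame(source_id = c("B", "E"), target_id = c("A", "F"),
                   score = c(0.9, 0.7), origin = "s2")
  m <- suppressMessages(merge_ppi_sources(list(t1, t2)))
  expect_equal(nrow(m), 3)
  ab <- m[pharmnet:::unordered_key(m$source_id, m$target_id) == pharmnet:::unordered_key("A", "B"), ]
  expect_equal(ab$score, 0.9)
  expect_equal(ab$origin, "s1,s2")

  d1 <- data.frame(source_id = paste0("a", 1:3), target_id = paste0("b", 1:3),
                   score = 0.5, origin = "s1")
  d2 <- data.frame(source_id = paste0("c", 1:4), target_id = paste0("d", 1:4),
                   score = 0.5, origin = "s2")
  expect_equal(nrow(suppressMessages(merge_ppi_sources(list(d1, d2)))), 7)
})

test_that("merged edge counts and record invariants hold on random tables", {
  set.seed(11)
  for (rep in 1:10) {
    tabs <- lapply(1:3, function(i) {
      n <- sample(5:20, 1)
      df <- data.frame(source_id = sample(LETTERS[1:8], n, replace = TRUE),
                       target_id = sample(LETTERS[1:8], n, replace = TRUE),
                       score = round(runif(n, 0.41, 1), 3),
                       origin = paste0("s", i))
      df <- df[df$source_id != df$target_id, , drop = FALSE]
      suppressMessages(pharmnet:::collapse_unordered(df))
    })
    m <- suppressMessages(merge_ppi_sources(tabs))
    expect_lte(nrow(m), sum(vapply(tabs, nrow, integer(1))))
    expect_true(all(m$score > 0.4 & m$score <= 1))
    expect_true(all(m$source_id != m$target_id))
    expect_false(anyDuplicated(pharmnet:::unordered_key(m$source_id, m$target_id)) > 0)
  }
})

test_that("annotation tables read from GMT with term gene sets in background", {
  d <- paper_fixture_dir()
  ann <- suppressMessages(read_annotation_table(file.path(d, "annotations.gmt")))
  expect_s3_class(ann, "annotation_table")
  expect_length(ann$terms, 30)
  for (tm in ann$terms) expect_true(all(tm$genes %in% ann$background))

  tsv <- write_tsv_lines(c("term_id\tterm_name\tgene_ids",
                           "GO:1\talpha\tA,B,C", "GO:2\tbeta\tB,D"))
  ann2 <- suppressMessages(read_annotation_table(tsv))
  expect_equal(ann2$terms[["GO:1"]]$genes, c("A", "B", "C"))
  expect_setequal(ann2$background, c("A", "B", "C", "D"))
})
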