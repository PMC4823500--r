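# Shared fixtures built in code. The paper-scale bundle takes ~1 s to
# generate, so it is memoized for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

paper_bundle <- function(seed = 1) {
  key <- paste0("bundle_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- suppressMessages(
      generate_study(paper_scale_config(seed = seed)))
  }
  .fixture_cache[[key]]
}

paper_fixture_dir <- function(seed = 1) {
  key <- paste0("dir_", seed)
  if (is.null(.fixture_cache[[key]])) {
    d <- file.path(tempdir(), paste0("paper_fixture_", seed))
    suppressMessages(write_fixture(paper_bundle(seed), d))
    .fixture_cache[[key]] <- d
  }
  .fixture_cache[[key]]
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal single-herb study written to a directory
minimal_fixture_dir <- function() {
  d <- tempfile("minimal_")
  dir.create(d)
  writeLines(c("herb_id\tcompound_id", "H1\tC1"),
             file.path(d, "compounds.tsv"))
  writeLines(c("chemical\tprotein\tscore", "C1\tT1\t0.9"),
             file.path(d, "compound_interactions.tsv"))
  writeLines(c("target_id", "T1", "D1"), file.path(d, "disease_targets.tsv"))
  writeLines(c("source_id\ttarget_id\tscore", "T1\tP1\t0.8", "P1\tD1\t0.7"),
             file.path(d, "ppi_source_a.tsv"))
  writeLines(c("source_id\ttarget_id\tscore", "T1\tD1\t0.6"),
             file.path(d, "ppi_source_b.tsv"))
  writeLines("GO:0000001\ttiny process\tT1\tP1\tD1\tQ1",
             file.path(d, "annotations.gmt"))
  d
}
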