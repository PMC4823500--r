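#' @importFrom utils read.delim write.table packageVersion combn head
#' @importFrom stats setNames
NULL

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty input file: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "", comment.char = "")
  if (nrow(df) == 0) stop("empty input file (header only): ", path, call. = FALSE)
  df
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a herb-compound table
#'
#' Reads a headered TSV with columns `herb_id` and `compound_id` (optional
#' `compound_name`), one row per herb-compound pair. Duplicate
#' (herb, compound) rows are collapsed with a warning. A compound may belong
#' to more than one herb.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with columns `herb_id`, `compound_id`,
#'   `compound_name`; one row per unique (herb, compound) pair.
#' @export
read_compound_table <- function(path) {
  df <- read_tsv_checked(path)
  require_columns(df, c("herb_id", "compound_id"), path)
  if (!"compound_name" %in% names(df)) df$compound_name <- df$compound_id
  df <- df[, c("herb_id", "compound_id", "compound_name")]
  df$herb_id <- as.character(df$herb_id)
  df$compound_id <- as.character(df$compound_id)
  if (any(!nzchar(df$compound_id))) {
    stop("schema error in ", path, ": empty compound_id", call. = FALSE)
  }
  key <- paste(df$herb_id, df$compound_id, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(n_dup, " duplicate (herb, compound) row(s) collapsed in ", path,
            call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  message("read_compound_table: ", nrow(df), " herb-compound records (",
          length(unique(df$compound_id)), " distinct compounds, ",
          length(unique(df$herb_id)), " herbs)")
  rownames(df) <- NULL
  df
}

# Score dialect: real-valued [0,1] scores, or STRING/STITCH-style integer
# 0-1000 scores (any value > 1 switches the whole column to /1000).
normalize_scores <- function(score, path) {
  raw <- score
  score <- suppressWarnings(as.numeric(score))
  bad <- which(is.na(score) & !is.na(raw))
  bad <- c(bad, which(is.na(raw)))
  if (length(bad) > 0) {
    stop("unparseable score in ", path, " at data row(s) ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  }
  if (any(score > 1)) score <- score / 1000
  if (any(score < 0 | score > 1)) {
    stop("score out of [0,1] after dialect normalization in ", path,
         call. = FALSE)
  }
  score
}

unordered_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read a scored interaction table
#'
#' Reads chemical-protein or protein-protein interaction records with a
#' confidence score. Accepts real-valued scores in \[0,1\] or the STRING/STITCH
#' integer 0-1000 dialect (auto-detected, divided by 1000). Keeps only
#' records with score strictly greater than `min_score`, drops self-loops,
#' and collapses duplicate unordered pairs keeping the maximum score.
#'
#' @param path Path to a TSV with columns `source_id`, `target_id`, `score`
#'   (aliases `chemical`/`protein` are accepted for the first two).
#' @param min_score Strict lower bound on the retained confidence score,
#'   in \[0,1\]. Default 0.4, the conventional medium-confidence cutoff.
#' @param origin Label recorded on each record; defaults to the file name.
#' @return data.frame with columns `source_id`, `target_id`, `score`,
#'   `origin`. May have zero rows (with a warning) if everything is filtered.
#' @export
read_interaction_table <- function(path, min_score = 0.4, origin = NULL) {
  stopifnot(is.numeric(min_score), length(min_score) == 1,
            min_score >= 0, min_score <= 1)
  df <- read_tsv_checked(path)
  if (all(c("chemical", "protein") %in% names(df))) {
    names(df)[match(c("chemical", "protein"), names(df))] <-
      c("source_id", "target_id")
  }
  require_columns(df, c("source_id", "target_id", "score"), path)
  if (is.null(origin)) origin <- tools::file_path_sans_ext(basename(path))
  n_in <- nrow(df)
  rec <- data.frame(source_id = as.character(df$source_id),
                    target_id = as.character(df$target_id),
                    score = normalize_scores(df$score, path),
                    origin = origin,
                    stringsAsFactors = FALSE)
  rec <- rec[rec$score > min_score, , drop = FALSE]          # strict >
  n_score <- n_in - nrow(rec)
  self <- rec$source_id == rec$target_id
  rec <- rec[!self, , drop = FALSE]
  rec <- collapse_unordered(rec)
  message("read_interaction_table: ", path, ": ", n_in, " rows in, ",
          n_score, " below score ", min_score, ", ", sum(self),
          " self-loops, ", nrow(rec), " records kept")
  if (nrow(rec) == 0) {
    warning("all interaction records filtered out in ", path, call. = FALSE)
  }
  rownames(rec) <- NULL
  rec
}

# Collapse duplicate unordered pairs, keeping max score and the union of
# origin labels (comma-joined, sorted).
collapse_unordered <- function(rec) {
  if (nrow(rec) == 0) return(rec)
  key <- unordered_key(rec$source_id, rec$target_id)
  if (!anyDuplicated(key)) return(rec)
  parts <- split(seq_len(nrow(rec)), key)
  out <- lapply(parts, function(idx) {
    r <- rec[idx, , drop = FALSE]
    best <- which.max(r$score)
    r2 <- r[best, , drop = FALSE]
    r2$origin <- paste(sort(unique(unlist(strsplit(r$origin, ",")))),
                       collapse = ",")
    r2
  })
  out <- do.call(rbind, out)
  out <- out[order(match(names(parts), unique(key))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a disease-target list
#'
#' One protein identifier per row; an optional single-column header
#' `target_id` is tolerated. Duplicates are removed.
#'
#' @param path Path to the list file.
#' @param disease_label Label for the target set; defaults to the file name.
#' @return A list with elements `disease_label` (string) and `target_ids`
#'   (character vector of unique identifiers).
#' @export
read_disease_targets <- function(path, disease_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (length(ids) > 0 && identical(tolower(ids[1]), "target_id")) {
    ids <- ids[-1]
  }
  if (length(ids) == 0) stop("empty disease-target file: ", path, call. = FALSE)
  ids <- unique(ids)
  if (is.null(disease_label)) {
    disease_label <- tools::file_path_sans_ext(basename(path))
  }
  message("read_disease_targets: ", length(ids), " unique targets for ",
          disease_label)
  list(disease_label = disease_label, target_ids = ids)
}

#' Merge PPI edge lists from several sources
#'
#' Union over unordered protein pairs; on conflict the maximum score is kept
#' and all source origins are recorded.
#'
#' @param tables List of interaction data.frames as returned by
#'   [read_interaction_table()] (already score-filtered).
#' @return One merged interaction data.frame.
#' @export
merge_ppi_sources <- function(tables) {
  stopifnot(is.list(tables))
  tables <- Filter(function(t) nrow(t) > 0, tables)
  if (length(tables) == 0) {
    return(data.frame(source_id = character(), target_id = character(),
                      score = numeric(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  rec <- do.call(rbind, tables)
  rec <- collapse_unordered(rec)
  message("merge_ppi_sources: ", nrow(rec), " unique edges from ",
          length(tables), " source table(s)")
  rownames(rec) <- NULL
  rec
}

#' Read a term-gene annotation table
#'
#' Accepts either GMT (term id, description, then one gene per tab field) or
#' a headered TSV with columns `term_id`, `term_name`, `gene_ids`
#' (comma-separated). The background defaults to the union of all annotated
#' genes.
#'
#' @param path Path to a `.gmt` or `.tsv` annotation file.
#' @return A list of class `annotation_table` with elements `terms` (named
#'   list: term_id -> list(term_name, genes)) and `background` (character).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  terms <- list()
  if (ext == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) stop("empty annotation file: ", path, call. = FALSE)
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) {
        stop("malformed GMT line (need term, description, >=1 gene): ",
             substr(ln, 1, 60), call. = FALSE)
      }
      genes <- unique(f[-(1:2)])
      genes <- genes[nzchar(genes)]
      if (f[1] %in% names(terms)) {
        stop("duplicate term_id in ", path, ": ", f[1], call. = FALSE)
      }
      terms[[f[1]]] <- list(term_name = f[2], genes = genes)
    }
  } else {
    df <- read_tsv_checked(path)
    require_columns(df, c("term_id", "term_name", "gene_ids"), path)
    if (anyDuplicated(df$term_id)) {
      stop("duplicate term_id in ", path, call. = FALSE)
    }
    for (i in seq_len(nrow(df))) {
      genes <- unique(trimws(strsplit(df$gene_ids[i], ",", fixed = TRUE)[[1]]))
      genes <- genes[nzchar(genes)]
      terms[[as.character(df$term_id[i])]] <-
        list(term_name = as.character(df$term_name[i]), genes = genes)
    }
  }
  background <- sort(unique(unlist(lapply(terms, `[[`, "genes"))))
  message("read_annotation_table: ", length(terms), " terms over ",
          length(background), " background genes")
  structure(list(terms = terms, background = background),
            class = "annotation_table")
}
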