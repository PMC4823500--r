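check_counts <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (!all(is.finite(c(k, n, K, N))) ||
      any(c(k, n, K, N) != round(c(k, n, K, N)))) {
    stop("counts must be finite integers", call. = FALSE)
  }
  if (n <= 0 || K <= 0) {
    stop("undefined term: n and K must be positive", call. = FALSE)
  }
  if (n > N || K > N || k < 0 || k > min(n, K)) {
    stop("invalid counts: need 0 <= k <= min(n, K), n <= N, K <= N",
         call. = FALSE)
  }
}

#' Fold enrichment
#'
#' Over-representation ratio (k/n)/(K/N) of a term with K of N background
#' genes among a study set of n genes containing k term genes.
#'
#' @param k Study genes in the term.
#' @param n Annotated study genes.
#' @param K Background genes in the term.
#' @param N Background size.
#' @return The fold enrichment (0 when k = 0).
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  (k / n) / (K / N)
}

#' Hypergeometric upper-tail p-value
#'
#' P(X >= k) for X hypergeometric with K successes in a background of N,
#' drawing n. With `ease = TRUE` the tail is computed with one study success
#' removed, P(X >= k-1) — the conservative EASE variant used by annotation
#' servers. k = 0 gives 1.
#'
#' @inheritParams fold_enrichment
#' @param ease Use the k-1 (EASE) variant.
#' @return p-value in (0, 1\].
#' @export
hypergeom_pvalue <- function(k, n, K, N, ease = FALSE) {
  check_counts(k, n, K, N)
  kk <- if (ease) max(k - 1, 0) else k
  # P(X >= kk) = P(X > kk - 1)
  stats::phyper(kk - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Functional-term enrichment of a study gene set
#'
#' For every annotation term containing at least one study gene, computes
#' the count quadruple (k, n, K, N), the fold enrichment, and the
#' hypergeometric (or EASE) p-value. Study genes absent from the background
#' are dropped with a warning. Results are sorted by ascending p, ties
#' broken by descending fold then term id.
#'
#' @param study Character vector of study gene ids.
#' @param annotations An `annotation_table` from [read_annotation_table()]
#'   (or built in code: list with `terms` and `background`).
#' @param background Optional character vector restricting the background;
#'   default is the annotation table's own background (all annotated genes).
#' @param ease Use the EASE (k-1) p-value variant (default TRUE).
#' @param correction `"none"` (default) or `"BH"` to append
#'   Benjamini-Hochberg q-values.
#' @return data.frame with columns `term_id`, `term_name`, `k`, `n`, `K`,
#'   `N`, `fold`, `p` (and `q` under BH), zero rows if no study gene is
#'   annotated to any term.
#' @export
enrich <- function(study, annotations, background = NULL, ease = TRUE,
                   correction = c("none", "BH")) {
  correction <- match.arg(correction)
  bg <- if (is.null(background)) annotations$background else unique(background)
  study <- unique(study)
  in_bg <- study %in% bg
  if (!any(in_bg)) {
    stop("study set disjoint from background; offending identifiers: ",
         paste(head(study, 10), collapse = ", "), call. = FALSE)
  }
  if (any(!in_bg)) {
    warning(sum(!in_bg), " study gene(s) absent from background dropped: ",
            paste(head(study[!in_bg], 5), collapse = ", "), call. = FALSE)
  }
  study <- study[in_bg]
  n <- length(study)
  N <- length(bg)
  rows <- lapply(names(annotations$terms), function(id) {
    tm <- annotations$terms[[id]]
    genes <- intersect(tm$genes, bg)
    K <- length(genes)
    if (K == 0) return(NULL)
    k <- length(intersect(study, genes))
    if (k == 0) return(NULL)
    data.frame(term_id = id, term_name = tm$term_name,
               k = k, n = n, K = K, N = N,
               fold = fold_enrichment(k, n, K, N),
               p = hypergeom_pvalue(k, n, K, N, ease = ease),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    warning("no study gene is annotated to any term", call. = FALSE)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$p, -res$fold, res$term_id), , drop = FALSE]
  if (correction == "BH") res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Write an enrichment table as TSV
#'
#' @param result Output of [enrich()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_tsv <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
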