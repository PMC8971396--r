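# The additive 0-5 score: one point per evidence flag, NA when any flag is
# missing (strict mode), "high scoring" at >= 3 of 5.

FLAG_COLS <- c("de_novo", "index", "ccr99", "gtex", "gnomad_lof")

#' Score genes from their five evidence flags
#'
#' Each gene scores one point per `TRUE` flag among the five final metrics
#' (de novo burden, exon index, CCR 99th percentile, brain expression,
#' LOF constraint), for a total of 0-5. In strict mode (default) any missing
#' flag makes the score NA, mirroring genes absent from at least one metric
#' source; in lenient mode missing flags count as `FALSE`. A gene is "high
#' scoring" when its score is at least `high_cutoff`; NA genes are never
#' high scoring. The percent column is the score as a fraction of the five
#' possible points (0, 20, ..., 100).
#'
#' @param flags data.frame with logical columns `de_novo`, `index`, `ccr99`,
#'   `gtex`, `gnomad_lof`, and optionally `symbol`.
#' @param strict_na If `TRUE` (default) a missing flag yields an NA score.
#' @param high_cutoff Minimum score for the high-scoring designation.
#' @return Input data.frame with `score` (integer or NA), `percent`
#'   (0-100 or NA) and `high_scoring` (logical, never NA) appended; rows
#'   ordered by `symbol` when present. Duplicate symbols are an error.
#' @export
score_genes <- function(flags, strict_na = TRUE, high_cutoff = 3) {
  miss <- setdiff(FLAG_COLS, names(flags))
  if (length(miss)) stop("missing flag columns: ", paste(miss, collapse = ", "))
  if ("symbol" %in% names(flags)) {
    dup <- unique(flags$symbol[duplicated(flags$symbol)])
    if (length(dup))
      stop("duplicate gene symbols: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  fm <- as.matrix(flags[, FLAG_COLS, drop = FALSE])
  if (!is.logical(fm)) storage.mode(fm) <- "logical"
  score <- as.integer(rowSums(fm, na.rm = !strict_na))
  if (strict_na) score[rowSums(is.na(fm)) > 0L] <- NA_integer_
  flags$score <- score
  flags$percent <- 20 * as.numeric(score)
  flags$high_scoring <- !is.na(score) & score >= high_cutoff
  if ("symbol" %in% names(flags)) {
    flags <- flags[order(flags$symbol), , drop = FALSE]
    rownames(flags) <- NULL
  }
  flags
}

#' Profile the score distribution of a gene set
#'
#' Summarizes a set of genes against a scored table: counts per score level
#' (NA included), the high-scoring members, and the maximum / median / mean
#' score expressed in percent. Genes absent from the scored table count as
#' NA. Medians of even-length sets are the mean of the two middle values;
#' NA genes are excluded from the median/mean but counted in the totals.
#'
#' @param symbols Character vector of gene symbols (nonempty).
#' @param scores Scored gene table from [score_genes()] (needs `symbol`,
#'   `score`, `percent`, `high_scoring`).
#' @return Object of class `score_profile`: `total_genes`, `scored_genes`,
#'   `counts_by_level` (named vector over 0..5 and NA), `high_scoring_genes`,
#'   `max_score`, `median_percent`, `mean_percent`.
#' @export
profile_gene_set <- function(symbols, scores) {
  if (length(symbols) == 0L) stop("empty gene set")
  stopifnot(all(c("symbol", "score", "high_scoring") %in% names(scores)))
  idx <- match(symbols, scores$symbol)
  sc <- scores$score[idx]             # NA for absent genes too
  high <- symbols[!is.na(idx) & scores$high_scoring[idx]]
  counts <- vapply(0:5, function(l) sum(sc == l, na.rm = TRUE), integer(1))
  counts <- c(stats::setNames(counts, as.character(0:5)), "NA" = sum(is.na(sc)))
  non_na <- sc[!is.na(sc)]
  structure(list(
    total_genes = length(symbols),
    scored_genes = length(non_na),
    counts_by_level = counts,
    high_scoring_genes = sort(high),
    max_score = if (length(non_na)) max(non_na) else NA_integer_,
    median_percent = score_median(20 * non_na),
    mean_percent = if (length(non_na)) mean(20 * non_na) else NA_real_
  ), class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat("Score profile:", x$total_genes, "genes,", x$scored_genes, "scored,",
      length(x$high_scoring_genes), "high scoring\n")
  print(x$counts_by_level)
  cat(sprintf("  max %s, median %.1f%%, mean %.1f%%\n",
              x$max_score, x$median_percent, x$mean_percent))
  invisible(x)
}

#' Pool score-level rows of an outcome-count table
#'
#' Element-wise sum of the selected score-level rows across outcome columns,
#' e.g. pooling levels 3, 4 and 5 into the ">= 3 of 5" row.
#'
#' @param counts data.frame or matrix with a `level` column/rownames in
#'   0..5 and numeric outcome-count columns.
#' @param levels Integer set within 0..5 to pool.
#' @return Named numeric vector: the pooled counts per outcome column.
#' @export
aggregate_levels <- function(counts, levels) {
  counts <- as.data.frame(counts)
  if (!("level" %in% names(counts)))
    stop("counts must carry a 'level' column")
  if (!all(levels %in% 0:5)) stop("levels must lie in 0..5")
  unknown <- setdiff(levels, counts$level)
  if (length(unknown))
    stop("levels absent from table: ", paste(unknown, collapse = ", "))
  sel <- counts[counts$level %in% levels, setdiff(names(counts), "level"),
                drop = FALSE]
  num <- vapply(sel, is.numeric, logical(1))
  colSums(sel[, num, drop = FALSE])
}
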