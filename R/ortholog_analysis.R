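# Mouse-ortholog phenotype enrichment: 1:1 human-mouse pairing under the
# published exclusion rules, then per-phenotype chi-squared tests and
# phenotype-class odds ratios for high-scoring genes.

#' Filter human-mouse ortholog pairs to analyzable 1:1 records
#'
#' Exclusions, in order: mouse genes whose human homolog resolves to two or
#' more distinct human genes (`multi_human`); multiple mouse genes matched
#' to the same human gene (`multi_mouse`); pairs with no phenotype data at
#' all (`no_phenotype`). Retained records form a bijection between their
#' human and mouse gene sets and carry at least one phenotype flag.
#'
#' @param pairs data.frame: `human_symbol`, `mouse_symbol`, optional
#'   `mgi_id`.
#' @param phenotypes data.frame: `mouse_symbol` plus one logical/0-1 column
#'   per high-level phenotype term. A mouse gene absent from this table
#'   counts as having no phenotype data.
#' @return List: `records` (retained pairs joined with their phenotype
#'   flags and `n_phenotypes`), `exclusions` (named counts by reason;
#'   reasons + retained sum to the input pair count).
#' @export
filter_orthologs <- function(pairs, phenotypes) {
  stopifnot(all(c("human_symbol", "mouse_symbol") %in% names(pairs)),
            "mouse_symbol" %in% names(phenotypes))
  n_in <- nrow(pairs)
  flag_cols <- setdiff(names(phenotypes), "mouse_symbol")

  multi_h <- unique(pairs$mouse_symbol[
    pairs$mouse_symbol %in% pairs$mouse_symbol[
      !duplicated(pairs[, c("human_symbol", "mouse_symbol")]) &
        duplicated(pairs$mouse_symbol)]])
  # a mouse gene linked to >= 2 distinct human genes
  tab_h <- table(unique(pairs[, c("human_symbol", "mouse_symbol")])$mouse_symbol)
  multi_h <- names(tab_h)[tab_h >= 2]
  keep1 <- !(pairs$mouse_symbol %in% multi_h)
  n_multi_human <- sum(!keep1)
  p1 <- pairs[keep1, , drop = FALSE]

  tab_m <- table(unique(p1[, c("human_symbol", "mouse_symbol")])$human_symbol)
  multi_m <- names(tab_m)[tab_m >= 2]
  keep2 <- !(p1$human_symbol %in% multi_m)
  n_multi_mouse <- sum(!keep2)
  p2 <- p1[keep2, , drop = FALSE]

  idx <- match(p2$mouse_symbol, phenotypes$mouse_symbol)
  fl <- phenotypes[idx, flag_cols, drop = FALSE]
  fl[] <- lapply(fl, function(x) !is.na(x) & as.logical(x))
  has_pheno <- !is.na(idx) & rowSums(as.matrix(fl)) > 0
  n_no_pheno <- sum(!has_pheno)

  records <- cbind(p2[has_pheno, , drop = FALSE],
                   fl[has_pheno, , drop = FALSE])
  records$n_phenotypes <- as.integer(rowSums(as.matrix(
    records[, flag_cols, drop = FALSE])))
  rownames(records) <- NULL

  list(records = records,
       exclusions = c(multi_human = n_multi_human,
                      multi_mouse = n_multi_mouse,
                      no_phenotype = n_no_pheno,
                      retained = nrow(records)))
}

#' Per-phenotype enrichment of high-scoring genes
#'
#' One chi-squared test (no continuity correction by default) per
#' high-level phenotype: high-scoring membership of the human gene against
#' presence of the phenotype in the mouse ortholog, Bonferroni-corrected
#' across the phenotype vocabulary.
#'
#' @param records Filtered ortholog records ([filter_orthologs()]).
#' @param high_scoring Character vector of high-scoring human symbols.
#' @param phenotype_cols Phenotype column names; defaults to every logical
#'   column of `records` except bookkeeping columns.
#' @param alpha Bonferroni-corrected level; default `0.05 / 27` rounded to
#'   the conventional 0.002.
#' @param yates Continuity correction, default `FALSE`.
#' @return data.frame per phenotype: counts, `or`, `ci_low`, `ci_high`,
#'   `statistic`, `p`, `significant`; degenerate phenotypes (all-positive
#'   or zero-positive) are skipped with NA p.
#' @export
phenotype_enrichment <- function(records, high_scoring,
                                 phenotype_cols = NULL, alpha = 0.002,
                                 yates = FALSE) {
  if (is.null(phenotype_cols)) {
    phenotype_cols <- names(records)[vapply(records, is.logical, logical(1))]
    phenotype_cols <- setdiff(phenotype_cols, c("high_scoring"))
  }
  hs <- records$human_symbol %in% high_scoring
  rows <- lapply(phenotype_cols, function(ph) {
    f <- records[[ph]]
    base <- data.frame(phenotype = ph,
                       high_with = sum(hs & f), high_without = sum(hs & !f),
                       other_with = sum(!hs & f), other_without = sum(!hs & !f))
    if (length(unique(f)) < 2L || length(unique(hs)) < 2L) {
      return(cbind(base, or = NA, ci_low = NA, ci_high = NA,
                   statistic = NA, p = NA))
    }
    tab <- matrix(c(base$high_with, base$high_without,
                    base$other_with, base$other_without), 2, byrow = TRUE)
    orr <- odds_ratio_2x2(tab)
    ct <- chi2_test(tab, yates = yates)
    cbind(base, or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
          statistic = ct$statistic, p = ct$p)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "alpha") <- alpha
  rownames(out) <- NULL
  out
}

#' Odds ratios for broad phenotype classes
#'
#' Collapses the phenotype vocabulary into broad classes (e.g. behavioral,
#' central/peripheral nervous system, non-neurological) — a gene carries a
#' class when any of the class's phenotype flags is set — and returns the
#' 2x2 odds ratio of high-scoring membership against each class.
#'
#' @param records Filtered ortholog records.
#' @param high_scoring Character vector of high-scoring human symbols.
#' @param classes Named list mapping class name to a character vector of
#'   phenotype column names.
#' @return data.frame per class: counts, `or`, `ci_low`, `ci_high`, `p`.
#' @export
phenotype_class_or <- function(records, high_scoring, classes) {
  stopifnot(is.list(classes), length(names(classes)) == length(classes))
  hs <- records$human_symbol %in% high_scoring
  rows <- lapply(names(classes), function(cl) {
    cols <- classes[[cl]]
    miss <- setdiff(cols, names(records))
    if (length(miss)) stop("unknown phenotype columns: ",
                           paste(miss, collapse = ", "))
    f <- rowSums(as.matrix(records[, cols, drop = FALSE])) > 0
    tab <- matrix(c(sum(hs & f), sum(hs & !f), sum(!hs & f), sum(!hs & !f)),
                  2, byrow = TRUE)
    r <- odds_ratio_2x2(tab)
    data.frame(class = cl, high_with = tab[1, 1], high_without = tab[1, 2],
               other_with = tab[2, 1], other_without = tab[2, 2],
               or = r$or, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
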