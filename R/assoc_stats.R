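# Contingency-table machinery used throughout: Pearson chi-squared, two-sided
# Fisher exact, cross-product odds ratios with Woolf intervals, per-metric
# screening, per-score-level odds ratios, the probability transform, and the
# minimum-detectable-OR power computation.

#' Pearson chi-squared test on a 2x2 table
#'
#' @param counts 2x2 nonnegative integer matrix.
#' @param yates Apply the continuity correction (off by default).
#' @return [assoc_result()] with statistic, df = 1 and two-sided p.
#' @export
chi2_test <- function(counts, yates = FALSE) {
  counts <- check_counts(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal total: chi-squared undefined")
  ct <- stats::chisq.test(counts, correct = yates)
  assoc_result("chi2", statistic = ct$statistic, df = ct$parameter,
               p = ct$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the minimum-likelihood rule: the sum of hypergeometric
#' point probabilities no larger than that of the observed table.
#'
#' @param counts 2x2 nonnegative integer matrix.
#' @param sided `"two_sided"` (default), `"less"` or `"greater"`.
#' @return [assoc_result()] with the exact p (no statistic).
#' @export
fisher_exact <- function(counts, sided = c("two_sided", "less", "greater")) {
  counts <- check_counts(counts)
  sided <- match.arg(sided)
  alt <- switch(sided, two_sided = "two.sided", less = "less",
                greater = "greater")
  ft <- stats::fisher.test(counts, alternative = alt)
  assoc_result("fisher", p = min(ft$p.value, 1))
}

#' Cross-product odds ratio of a 2x2 table with Woolf interval
#'
#' OR = (a d) / (b c) for the table \[\[a, b\], \[c, d\]\], with a Woolf
#' log-scale confidence interval (log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))
#' and a chi-squared p-value. When any cell is zero the Haldane--Anscombe
#' correction adds 0.5 to every cell (noted in the result). This equals the
#' exponentiated coefficient of a one-predictor logistic regression on the
#' expanded data.
#'
#' @param counts 2x2 matrix: rows = exposure (exposed first), columns =
#'   outcome (event first).
#' @param ci_level Confidence level, default 0.95.
#' @return [assoc_result()] with `or`, `ci_low`, `ci_high`, p.
#' @export
odds_ratio_2x2 <- function(counts, ci_level = 0.95) {
  counts <- check_counts(counts)
  if (any(rowSums(counts) == 0))
    stop("a row of the 2x2 table is all zero: odds ratio undefined")
  note <- NULL
  work <- counts
  if (any(work == 0)) {
    work <- work + 0.5
    note <- "Haldane-Anscombe 0.5 correction applied (zero cell)"
  }
  or <- (work[1, 1] * work[2, 2]) / (work[1, 2] * work[2, 1])
  se <- sqrt(sum(1 / work))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  # p from the score (chi-squared) test when well-defined, else Fisher
  p <- if (all(colSums(counts) > 0) && all(rowSums(counts) > 0)) {
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (any(counts <= 5) || any(expected < 5))
      min(stats::fisher.test(counts)$p.value, 1)
    else stats::chisq.test(counts, correct = FALSE)$p.value
  } else NA_real_
  assoc_result("or_2x2", p = p, or = or,
               ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
               note = note)
}

#' Screen candidate metrics against the outcome
#'
#' One Pearson chi-squared test per candidate flag against the binary
#' CNS-outcome label; a metric passes when its p-value is below `alpha`.
#' Constant (no-variation) metrics are flagged degenerate and fail.
#'
#' @param genes data.frame with logical candidate columns and a logical
#'   `cns` outcome column (genes with NA in a candidate are dropped for
#'   that candidate's test).
#' @param candidates Character vector of candidate column names.
#' @param alpha Screening level, default 0.05.
#' @return data.frame: `metric`, `statistic`, `p`, `pass`, `reason`.
#' @export
screen_metrics <- function(genes, candidates, alpha = 0.05) {
  stopifnot("cns" %in% names(genes), is.logical(genes$cns))
  miss <- setdiff(candidates, names(genes))
  if (length(miss)) stop("unknown candidates: ", paste(miss, collapse = ", "))
  res <- lapply(candidates, function(m) {
    f <- genes[[m]]
    ok <- !is.na(f) & !is.na(genes$cns)
    f <- f[ok]; y <- genes$cns[ok]
    if (length(unique(f)) < 2L || length(unique(y)) < 2L)
      return(data.frame(metric = m, statistic = NA_real_, p = NA_real_,
                        pass = FALSE, reason = "degenerate"))
    tab <- table(factor(f, c(TRUE, FALSE)), factor(y, c(TRUE, FALSE)))
    ct <- chi2_test(tab)
    data.frame(metric = m, statistic = ct$statistic, p = ct$p,
               pass = ct$p < alpha,
               reason = if (ct$p < alpha) "" else "screen_fail")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Odds ratios per score level against the zero-score reference
#'
#' For each score level (and the pooled `>= 3` row) builds the 2x2 of
#' outcome (CNS vs not) by membership (level vs reference level) and
#' returns the cross-product OR with Woolf interval. Genes with NA scores
#' are excluded. The pooled row equals [odds_ratio_2x2()] on the summed
#' per-level counts.
#'
#' @param genes data.frame with logical `cns` and integer `score` columns.
#' @param reference_level Score level of the comparison group, default 0.
#' @param high_cutoff Pooled row lower bound, default 3.
#' @return data.frame with one row per level (`"1"`..`"5"`, `">=3"`):
#'   the 2x2 cells and OR / CI / p (NA row for empty levels).
#' @export
score_level_or <- function(genes, reference_level = 0, high_cutoff = 3) {
  stopifnot(all(c("cns", "score") %in% names(genes)))
  g <- genes[!is.na(genes$score) & !is.na(genes$cns), , drop = FALSE]
  ref <- g[g$score == reference_level, , drop = FALSE]
  if (!nrow(ref)) stop("reference level ", reference_level, " is empty")
  ref_cells <- c(sum(ref$cns), sum(!ref$cns))
  lv_rows <- function(label, members) {
    if (!nrow(members)) {
      return(data.frame(level = label, n_cns = NA, n_not = NA,
                        ref_cns = ref_cells[1], ref_not = ref_cells[2],
                        or = NA, ci_low = NA, ci_high = NA, p = NA))
    }
    tab <- matrix(c(sum(members$cns), sum(!members$cns), ref_cells), 2,
                  byrow = TRUE)
    r <- odds_ratio_2x2(tab)
    data.frame(level = label, n_cns = tab[1, 1], n_not = tab[1, 2],
               ref_cns = tab[2, 1], ref_not = tab[2, 2],
               or = r$or, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
  }
  levels <- setdiff(1:5, reference_level)
  out <- do.call(rbind, c(
    lapply(levels, function(l) lv_rows(as.character(l),
                                       g[g$score == l, , drop = FALSE])),
    list(lv_rows(paste0(">=", high_cutoff),
                 g[g$score >= high_cutoff, , drop = FALSE]))))
  rownames(out) <- NULL
  out
}

#' Negative control: zero-score genes versus non-CNS phenotypes
#'
#' Tests whether genes that met no metric are enriched for non-CNS-related
#' phenotype labels, the expected mirror image of the main association.
#'
#' @param genes data.frame with a `score` column and an `outcome` column in
#'   `{"CNS", "NON_CNS", "NO_PHENOTYPE", "ABSENT"}`.
#' @return [assoc_result()]: OR of score-0 membership for the NON_CNS label.
#' @export
negative_control_or <- function(genes) {
  stopifnot(all(c("score", "outcome") %in% names(genes)))
  g <- genes[!is.na(genes$score), , drop = FALSE]
  zero <- g$score == 0
  if (!any(zero)) stop("no zero-score genes")
  non_cns <- g$outcome == "NON_CNS"
  tab <- matrix(c(sum(zero & non_cns), sum(zero & !non_cns),
                  sum(!zero & non_cns), sum(!zero & !non_cns)), 2, byrow = TRUE)
  odds_ratio_2x2(tab)
}

#' Convert an odds ratio to an absolute probability
#'
#' Given the baseline odds of the outcome in the reference group, the
#' probability in the exposed group is
#' `baseline_odds * or / (1 + baseline_odds * or)` — the logistic
#' likelihood curve evaluated at the shifted log-odds.
#'
#' @param or_value Odds ratio (> 0).
#' @param baseline_odds Odds of the outcome in the reference group (> 0).
#' @return Probability in (0, 1).
#' @export
probability_transform <- function(or_value, baseline_odds) {
  if (any(or_value <= 0) || any(baseline_odds <= 0))
    stop("odds ratio and baseline odds must be positive")
  k <- baseline_odds * or_value
  k / (1 + k)
}

#' Enrichment of a gene subset relative to the genome
#'
#' Compares the hit rate inside a subset with the rate in the rest of the
#' genome using non-overlapping cells: the subset is removed from the
#' genome complement so the 2x2 cells partition the genome.
#'
#' @param subset_hits,subset_n Hits and size of the subset.
#' @param genome_hits,genome_n Hits and size of the whole genome
#'   (including the subset).
#' @return [assoc_result()] with chi-squared p and cross-product OR.
#' @export
proportion_enrichment <- function(subset_hits, subset_n, genome_hits, genome_n) {
  if (subset_n > genome_n || subset_hits > genome_hits)
    stop("subset counts exceed genome counts")
  if (subset_hits > subset_n || genome_hits > genome_n)
    stop("hits exceed totals")
  tab <- matrix(c(subset_hits, subset_n - subset_hits,
                  genome_hits - subset_hits,
                  (genome_n - subset_n) - (genome_hits - subset_hits)),
                2, byrow = TRUE)
  r <- odds_ratio_2x2(tab)
  ct <- chi2_test(tab)
  assoc_result("chi2", statistic = ct$statistic, df = ct$df, p = ct$p,
               or = r$or, ci_low = r$ci_low, ci_high = r$ci_high)
}

# closed-form power of the two-sided two-proportion z test (unpooled SE for
# the alternative, pooled under the null), unequal group sizes allowed
two_prop_power <- function(p0, p1, n0, n1, alpha = 0.05) {
  pb <- (n0 * p0 + n1 * p1) / (n0 + n1)
  se0 <- sqrt(pb * (1 - pb) * (1 / n0 + 1 / n1))
  se1 <- sqrt(p0 * (1 - p0) / n0 + p1 * (1 - p1) / n1)
  za <- stats::qnorm(1 - alpha / 2)
  d <- abs(p1 - p0)
  stats::pnorm((d - za * se0) / se1) + stats::pnorm((-d - za * se0) / se1)
}

#' Minimum detectable odds ratio for a two-group comparison
#'
#' Smallest OR (> 1) at which a two-sided two-proportion test on groups of
#' the given sizes attains the requested power, found by bisection over the
#' OR. The exposed-group rate implied by a candidate OR is
#' `odds1 / (1 + odds1)` with `odds1 = OR * p0 / (1 - p0)`.
#'
#' @param n_exposed,n_reference Group sizes.
#' @param baseline_rate Outcome rate in the reference group, in (0, 1).
#' @param power Target power, default 0.95.
#' @param alpha Two-sided significance level, default 0.05.
#' @return The minimum detectable OR.
#' @export
min_detectable_or <- function(n_exposed, n_reference, baseline_rate,
                              power = 0.95, alpha = 0.05) {
  stopifnot(n_exposed > 0, n_reference > 0,
            baseline_rate > 0, baseline_rate < 1,
            power > 0, power < 1)
  pow <- function(or) {
    odds1 <- or * baseline_rate / (1 - baseline_rate)
    two_prop_power(baseline_rate, odds1 / (1 + odds1),
                   n_reference, n_exposed, alpha)
  }
  hi <- 2
  while (pow(hi) < power && hi < 1e6) hi <- hi * 2
  if (pow(hi) < power) stop("requested power unattainable")
  stats::uniroot(function(or) pow(or) - power, c(1 + 1e-9, hi),
                 tol = 1e-8)$root
}
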