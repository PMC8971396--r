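# Independent oracles and small builders used across the suite.

# textbook Pearson statistic, computed from first principles
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# two-sided Fisher p by full enumeration of the hypergeometric support:
# sum of point probabilities no larger than the observed table's
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(a, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# odds ratio via maximum-likelihood logistic regression on expanded rows
oracle_or_glm <- function(tab) {
  x <- rep(c(1, 1, 0, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  y <- rep(c(1, 0, 1, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  exp(stats::coef(stats::glm(y ~ x, family = stats::binomial()))[["x"]])
}

# a random valid flag table for scoring tests
random_flags <- function(n, na_rate = 0) {
  f <- as.data.frame(matrix(stats::runif(5 * n) < 0.4, n, 5))
  names(f) <- c("de_novo", "index", "ccr99", "gtex", "gnomad_lof")
  if (na_rate > 0) {
    for (c in names(f))
      f[[c]][stats::runif(n) < na_rate] <- NA
  }
  f$symbol <- sprintf("G%05d", seq_len(n))
  f
}

# tiny two-gene map: geneA (score 4) with exons on chr1 0-100 / 500-600,
# geneB (score 2) with one exon 1000-1100; geneC unscored at 2000-2100
tiny_map <- function() {
  list(
    gene_models = data.frame(
      chrom = "chr1",
      start = c(0L, 500L, 1000L, 2000L),
      end = c(100L, 600L, 1100L, 2100L),
      symbol = c("geneA", "geneA", "geneB", "geneC")),
    scores = data.frame(
      symbol = c("geneA", "geneB", "geneC"),
      score = c(4L, 2L, NA_integer_),
      percent = c(80, 40, NA),
      high_scoring = c(TRUE, FALSE, FALSE)))
}
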