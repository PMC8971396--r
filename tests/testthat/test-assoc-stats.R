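test_that("Pearson chi-squared matches the textbook formula", {
  r <- chi2_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)
  # all expected cells are 12.5 for this table; statistic is exactly 18
  tab <- matrix(c(20, 5, 5, 20), 2, byrow = TRUE)
  r <- chi2_test(tab)
  expect_equal(r$statistic, 18)
  expect_equal(r$p, stats::pchisq(18, 1, lower.tail = FALSE))
  set.seed(21)
  for (i in 1:50) {
    tab <- matrix(sample(10:60, 4), 2)
    expect_equal(chi2_test(tab)$statistic, oracle_chi2(tab),
                 tolerance = 1e-10)
  }
  expect_error(chi2_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(1, 2, 2))$p, 1)
  set.seed(22)
  for (i in 1:100) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(1, 3, 2)), "2x2")
})

test_that("cross-product OR with Woolf CI matches a logistic-fit oracle", {
  r <- odds_ratio_2x2(matrix(1, 2, 2))
  expect_equal(r$or, 1)
  expect_true(r$ci_low <= 1 && 1 <= r$ci_high)
  set.seed(23)
  for (i in 1:25) {
    tab <- matrix(sample(3:40, 4), 2)
    r <- odds_ratio_2x2(tab)
    expect_equal(r$or, oracle_or_glm(tab), tolerance = 1e-6)
    expect_equal(r$or, (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
  }
  # zero cell triggers the Haldane-Anscombe correction, and it is reported
  r <- odds_ratio_2x2(matrix(c(5, 0, 3, 7), 2, byrow = TRUE))
  expect_match(r$note, "Haldane")
  expect_equal(r$or, (5.5 * 7.5) / (0.5 * 3.5))
  expect_error(odds_ratio_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "all zero")
})

test_that("metric screening separates real from null associations", {
  g <- simulate_genome(
    n_genes = 8000, seed = 31,
    metric_or = c(de_novo = 2, index = 1, ccr99 = 1, gtex = 1,
                  gnomad_lof = 1),
    metric_freq = c(de_novo = 0.3, index = 0.3, ccr99 = 0.3, gtex = 0.3,
                    gnomad_lof = 0.3),
    baseline_prev = 0.15, missing_rate = 0)
  sc <- score_genes(compute_metric_flags(g))
  scr <- screen_metrics(sc, c("de_novo", "index"))
  expect_true(scr$pass[scr$metric == "de_novo"])
  expect_false(scr$pass[scr$metric == "index"])
  # constant metric is degenerate
  sc$always <- TRUE
  scr <- screen_metrics(sc, "always")
  expect_equal(scr$reason, "degenerate")
  expect_false(scr$pass)
})

test_that("per-level odds ratios are consistent and handle empty levels", {
  g <- data.frame(
    score = rep(c(0L, 1L, 2L, 3L), c(400, 300, 200, 100)),
    cns = c(rep(c(TRUE, FALSE), c(40, 360)), rep(c(TRUE, FALSE), c(60, 240)),
            rep(c(TRUE, FALSE), c(60, 140)), rep(c(TRUE, FALSE), c(50, 50))))
  res <- score_level_or(g)
  # a level with the same outcome composition as the reference has OR 1
  g2 <- g; g2$cns[g2$score == 1] <- rep(c(TRUE, FALSE), c(30, 270))
  r1 <- score_level_or(g2)
  expect_equal(r1$or[r1$level == "1"], 1, tolerance = 1e-12)
  # empty levels give NA rows
  expect_true(is.na(res$or[res$level == "5"]))
  # pooled >=3 row equals the OR of the summed counts
  pooled <- res[res$level == ">=3", ]
  tab <- matrix(c(sum(g$cns[g$score >= 3]), sum(!g$cns[g$score >= 3]),
                  sum(g$cns[g$score == 0]), sum(!g$cns[g$score == 0])),
                2, byrow = TRUE)
  expect_equal(pooled$or, odds_ratio_2x2(tab)$or)
  expect_error(score_level_or(data.frame(score = 1L, cns = TRUE)),
               "reference")
})

test_that("per-level ORs increase monotonically under an additive truth", {
  hits <- 0
  for (r in 1:20) {
    g <- simulate_genome(n_genes = 19601, rho = 0.35, seed = 500 + r,
                         missing_rate = 0)
    sc <- score_genes(compute_metric_flags(g))
    res <- score_level_or(sc)
    ors <- res$or[res$level %in% as.character(1:4)]
    if (all(diff(ors) > 0)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("the negative control mirrors the main association", {
  # outcome independent of score: OR compatible with 1
  g <- simulate_genome(n_genes = 15000, seed = 33, missing_rate = 0,
                       metric_or = c(de_novo = 1, index = 1, ccr99 = 1,
                                     gtex = 1, gnomad_lof = 1))
  r <- negative_control_or(score_genes(compute_metric_flags(g)))
  expect_true(r$ci_low <= 1 && 1 <= r$ci_high)
  # configured 1.7-fold enrichment of score-0 genes in non-CNS labels is
  # recovered within the interval in most replicate genomes
  hits <- 0
  for (rep in 1:20) {
    g <- simulate_genome(n_genes = 12000, seed = 600 + rep,
                         missing_rate = 0, non_cns_score0_or = 1.7,
                         metric_or = c(de_novo = 1, index = 1, ccr99 = 1,
                                       gtex = 1, gnomad_lof = 1))
    r <- negative_control_or(score_genes(compute_metric_flags(g)))
    if (r$ci_low <= 1.7 && 1.7 <= r$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 18)
  expect_error(negative_control_or(data.frame(score = 2L, outcome = "CNS")),
               "zero-score")
})

test_that("probability transform follows the logistic likelihood curve", {
  expect_equal(probability_transform(1, 1), 0.5)
  expect_equal(probability_transform(4.4, 1.204), 0.8412, tolerance = 1e-4)
  # monotone increasing in the OR
  p <- probability_transform(c(1, 2, 4, 8), 0.5)
  expect_true(all(diff(p) > 0))
  # symmetry: inverting both arguments reflects the probability
  for (or in c(0.3, 1.7, 6)) for (o in c(0.2, 1, 3))
    expect_equal(probability_transform(1 / or, 1 / o),
                 1 - probability_transform(or, o))
  expect_error(probability_transform(-1, 1), "positive")
})

test_that("subset enrichment uses non-overlapping cells", {
  # equal proportions: no signal
  r <- proportion_enrichment(50, 500, 200, 2000)
  expect_gt(r$p, 0.9)
  # brain-elevated-set counts give the cross-product OR of the
  # disjoint 2x2 [[301,2141],[1300,15017]]
  r <- proportion_enrichment(301, 2442, 1601, 18759)
  expect_equal(r$or, (301 * 15017) / (2141 * 1300), tolerance = 1e-12)
  expect_equal(r$or, 1.62, tolerance = 0.01)
  # OR is invariant to doubling all counts
  r2 <- proportion_enrichment(602, 4884, 3202, 37518)
  expect_equal(r2$or, r$or)
  expect_error(proportion_enrichment(10, 100, 5, 50), "exceed")
})

test_that("minimum detectable OR behaves like a power calculation", {
  a <- min_detectable_or(2000, 2000, 0.2)
  b <- min_detectable_or(4000, 4000, 0.2)
  expect_lt(b, a)                       # more samples, finer detection
  expect_lt(min_detectable_or(1e6, 1e6, 0.5), 1.02)  # asymptotic limit
  # Monte-Carlo check: simulating at the reported minimum OR achieves the
  # requested power within sampling error
  or <- min_detectable_or(1500, 1500, 0.25, power = 0.9)
  p0 <- 0.25
  odds1 <- or * p0 / (1 - p0); p1 <- odds1 / (1 + odds1)
  set.seed(24)
  rej <- replicate(4000, {
    x0 <- rbinom(1, 1500, p0); x1 <- rbinom(1, 1500, p1)
    suppressWarnings(prop.test(c(x1, x0), c(1500, 1500),
                               correct = FALSE)$p.value) < 0.05
  })
  expect_lt(abs(mean(rej) - 0.9), 0.05)
})
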