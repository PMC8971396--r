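test_that("CNV annotation summarizes overlapped genes by exon rule", {
  tm <- tiny_map()
  cnv <- data.frame(chrom = "chr1", start = 50L, end = 1050L)
  a <- annotate_cnvs(cnv, tm$gene_models, tm$scores)
  expect_equal(a$n_genes, 2L)
  expect_equal(a$max_level, 4L)
  expect_equal(a$median_percent, 60)
  expect_equal(a$mean_percent, 60)
  expect_equal(a$high_count, 1L)
  expect_equal(a$size_bp, 1000L)
  # CNV entirely inside an intron of geneA: no exon overlap, no genes
  intron <- data.frame(chrom = "chr1", start = 150L, end = 450L)
  a <- annotate_cnvs(intron, tm$gene_models, tm$scores)
  expect_equal(a$n_genes, 0L)
  expect_equal(nrow(filter_scored_cnvs(a)), 0L)
  # CNV over the unscored gene only: NA max, dropped from cohort analyses
  nac <- data.frame(chrom = "chr1", start = 1990L, end = 2150L)
  a <- annotate_cnvs(nac, tm$gene_models, tm$scores)
  expect_true(is.na(a$max_level))
  expect_equal(a$n_genes, 1L)
  f <- filter_scored_cnvs(a)
  expect_equal(nrow(f), 0L); expect_equal(attr(f, "n_dropped"), 1L)
  expect_error(annotate_cnvs(data.frame(chrom = "chrZ", start = 1L,
                                        end = 10L),
                             tm$gene_models, tm$scores), "absent")
})

test_that("annotation is invariant to gene-model row order", {
  tm <- tiny_map()
  cnv <- data.frame(chrom = "chr1", start = 0L, end = 2100L)
  a1 <- annotate_cnvs(cnv, tm$gene_models, tm$scores)
  set.seed(61)
  a2 <- annotate_cnvs(cnv, tm$gene_models[sample(4), ], tm$scores)
  expect_equal(a1, a2, ignore_attr = TRUE)
})

test_that("interval overlap agrees with a per-base membership oracle", {
  set.seed(62)
  for (rep in 1:20) {
    # random tiny genome on a 500 bp chromosome
    ex_start <- sort(sample(0:480, 6))
    gm <- data.frame(chrom = "chr1", start = ex_start,
                     end = pmin(ex_start + sample(5:30, 6, TRUE), 500L),
                     symbol = rep(c("g1", "g2", "g3"), each = 2))
    scores <- data.frame(symbol = c("g1", "g2", "g3"), score = c(3L, 1L, 0L),
                         percent = c(60, 20, 0),
                         high_scoring = c(TRUE, FALSE, FALSE))
    cnv <- data.frame(chrom = "chr1", start = sample(0:400, 1))
    cnv$end <- cnv$start + sample(10:100, 1)
    a <- annotate_cnvs(cnv, gm, scores)
    base_hits <- unique(gm$symbol[vapply(seq_len(nrow(gm)), function(i) {
      any(seq(gm$start[i], gm$end[i] - 1) %in% seq(cnv$start, cnv$end - 1))
    }, logical(1))])
    got <- if (a$n_genes) strsplit(a$genes, ";")[[1]] else character(0)
    expect_setequal(got, base_hits)
  }
})

test_that("gene_body mode annotates intron-only overlaps", {
  tm <- tiny_map()
  intron <- data.frame(chrom = "chr1", start = 150L, end = 450L)
  a <- annotate_cnvs(intron, tm$gene_models, tm$scores,
                     overlap = "gene_body")
  expect_equal(a$n_genes, 1L)
  expect_equal(attr(a, "overlap_mode"), "gene_body")
})

test_that("the aneuploidy guard excludes near-whole-chromosome CNVs", {
  tm <- tiny_map()
  cnv <- data.frame(chrom = "chr1", start = c(0L, 50L), end = c(2900L, 150L))
  expect_warning(
    a <- annotate_cnvs(cnv, tm$gene_models, tm$scores,
                       chrom_lengths = c(chr1 = 3000L)),
    "aneuploidy")
  expect_equal(nrow(a), 1L)
})

test_that("identical cohorts show no cohort differences", {
  g <- simulate_genome(n_genes = 2000, rho = 0.3, seed = 63)
  sc <- score_genes(compute_metric_flags(g))
  gm <- simulate_gene_map(sc$symbol, seed = 63)
  co <- simulate_cnv_cohorts(sc, gm, n_case = 300, n_control = 300,
                             enrichment_or = 1, seed = 63)
  a <- annotate_cnvs(co$cases, gm, sc)
  cc <- compare_cohorts(a, a)
  expect_true(all(abs(cc$statistic) < 1e-10, na.rm = TRUE))
  expect_false(any(cc$significant))
  r <- high_gene_or(a, a)
  expect_equal(r$or, 1)
})

test_that("a shifted case score distribution is detected", {
  g <- simulate_genome(n_genes = 4000, rho = 0.3, seed = 64)
  sc <- score_genes(compute_metric_flags(g))
  gm <- simulate_gene_map(sc$symbol, seed = 64)
  hits <- 0
  for (rep in 1:10) {
    co <- simulate_cnv_cohorts(sc, gm, n_case = 800, n_control = 800,
                               enrichment_or = 4, seed = 800 + rep)
    acs <- annotate_cnvs(co$cases, gm, sc)
    act <- annotate_cnvs(co$controls, gm, sc)
    cc <- compare_cohorts(acs, act)
    if (all(cc$significant[cc$test == "mean_percent"])) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("equal scores with tripled case sizes flags only the size tests", {
  g <- simulate_genome(n_genes = 3000, rho = 0.3, seed = 65)
  sc <- score_genes(compute_metric_flags(g))
  gm <- simulate_gene_map(sc$symbol, seed = 65)
  co <- simulate_cnv_cohorts(sc, gm, n_case = 700, n_control = 700,
                             enrichment_or = 1, seed = 65)
  acs <- annotate_cnvs(co$cases, gm, sc)
  act <- annotate_cnvs(co$controls, gm, sc)
  acs$size_bp <- acs$size_bp * 3L
  cc <- compare_cohorts(acs, act)
  expect_true(all(cc$significant[cc$test == "size_bp"]))
  expect_false(any(cc$significant[cc$test != "size_bp"]))
})

test_that("max-score levels partition each cohort stratum", {
  t3 <- load_fixture("table3_counts")
  s3 <- counts_to_summaries(t3)
  cases <- s3[s3$cohort == "case", ]
  controls <- s3[s3$cohort == "control", ]
  tab <- max_score_table(cases, controls)
  expect_equal(sum(tab$case_n[tab$stratum == "loss"]), 835)
  expect_equal(sum(tab$case_n[tab$stratum == "gain"]), 1357)
  expect_equal(sum(tab$control_n[tab$stratum == "loss"]), 2547)
  expect_equal(sum(tab$control_n[tab$stratum == "gain"]), 1862)
  # round-trip: rebuilt table equals the fixture counts
  m <- merge(tab, t3, by = c("stratum", "level"))
  expect_equal(m$case_n.x, m$case_n.y)
  expect_equal(m$control_n.x, m$control_n.y)
})

test_that("degenerate max-score levels are skipped, not tested", {
  s <- data.frame(cohort = "case", cnv_type = "loss", max_level = 0L,
                  n_genes = 1L, scored_genes = 1L, high_count = 0L)
  tab <- max_score_table(s[rep(1, 10), ], s[rep(1, 10), ])
  res <- max_score_tests(tab)
  expect_true(all(is.na(res$p[res$level != "0"])))
  expect_false(any(res$significant[res$level != "0"]))
})

test_that("subgroup comparisons are null for homogeneous groups and
           detect an injected shift", {
  g <- simulate_genome(n_genes = 2000, rho = 0.3, seed = 66)
  sc <- score_genes(compute_metric_flags(g))
  gm <- simulate_gene_map(sc$symbol, seed = 66)
  co <- simulate_cnv_cohorts(sc, gm, n_case = 300, n_control = 100,
                             seed = 66)
  a <- annotate_cnvs(co$cases, gm, sc)
  r <- subgroup_compare(a, "sex")
  expect_true(all(r$p > 0.001, na.rm = TRUE))
  # unknown-category CNVs are excluded and counted
  a2 <- a; a2$sex[1:5] <- "unknown"
  expect_equal(attr(subgroup_compare(a2, "sex"), "n_excluded"), 5L)
  # +10-point shift between inheritance groups, n = 40 per group
  hits <- 0
  for (rep in 1:10) {
    set.seed(900 + rep)
    b <- a[sample(nrow(a), 80), ]
    b$inheritance <- rep(c("maternal", "de_novo"), each = 40)
    b$mean_percent[b$inheritance == "de_novo"] <-
      b$mean_percent[b$inheritance == "de_novo"] + 10
    r <- subgroup_compare(b, "inheritance")
    if (r$p[r$measure == "mean_percent"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("pathogenicity regression recovers a per-class gene-count slope", {
  mk_cohort <- function(beta, seed, size_confound = FALSE) {
    set.seed(seed)
    n <- 400
    cls <- sample(1:4, n, replace = TRUE)
    size <- if (size_confound) exp(rnorm(n, 11 + 0.5 * cls, 0.3))
            else exp(rnorm(n, 12, 0.5))
    high <- rpois(n, lambda = pmax(0.2 + beta * cls +
                                     if (size_confound) 0 else 0, 0.01))
    if (size_confound) high <- rpois(n, 0.2 + size / 2e5)
    data.frame(classification = cls, size_bp = size, high_count = high,
               scored_genes = high + rpois(n, 3),
               n_genes = high + rpois(n, 3) + rpois(n, 1),
               median_percent = 10 + 5 * high + rnorm(n, 0, 8))
  }
  hits <- 0
  for (rep in 1:10) {
    d <- mk_cohort(0.5, 1000 + rep)
    r <- pathogenicity_regression(d)
    s <- r[r$outcome == "high_count", ]
    if (abs(s$slope - 0.5) < 2 * s$se) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # shuffled classification: slope compatible with zero
  d <- mk_cohort(0.5, 1099)
  d$classification <- sample(d$classification)
  r <- pathogenicity_regression(d)
  s <- r[r$outcome == "high_count", ]
  expect_lt(abs(s$slope), 3 * s$se)
  # size-only confound: adjusting for size removes the spurious slope
  d <- mk_cohort(0, 1100, size_confound = TRUE)
  with_adj <- pathogenicity_regression(d, adjust_size = TRUE)
  without <- pathogenicity_regression(d, adjust_size = FALSE)
  s1 <- with_adj[with_adj$outcome == "high_count", ]
  s0 <- without[without$outcome == "high_count", ]
  expect_gt(s0$slope / s0$se, 2)       # confounded slope looks real
  expect_lt(abs(s1$slope / s1$se), 2)  # covariate absorbs it
  expect_error(pathogenicity_regression(
    data.frame(classification = 1, size_bp = 1, high_count = 0,
               scored_genes = 0, n_genes = 0, median_percent = 0)),
    "classification levels")
})

test_that("region reports profile segments consistently with the region", {
  fx <- load_fixture("region_22q11")
  rr <- region_report(fx$region, fx$segments, fx$gene_models, fx$scores,
                      overlap = "gene_body")
  expect_equal(rr$region_profile$total_genes, 64L)
  # disjoint segments partition the region's genes
  seg_tot <- sum(vapply(rr$segment_profiles, `[[`, integer(1),
                        "total_genes"))
  expect_equal(seg_tot, rr$region_profile$total_genes)
  seg_counts <- Reduce(`+`, lapply(rr$segment_profiles, `[[`,
                                   "counts_by_level"))
  expect_equal(seg_counts, rr$region_profile$counts_by_level)
  # segment outside the region is an error
  bad <- data.frame(name = "Z", chrom = "chr22",
                    start = 10L, end = 99999999L)
  expect_error(region_report(fx$region, bad, fx$gene_models, fx$scores,
                             overlap = "gene_body"), "outside")
  # gene-free segment warns and yields an empty profile
  empt <- data.frame(name = "gap", chrom = "chr22",
                     start = 18900000L, end = 18900100L)
  expect_warning(r2 <- region_report(fx$region, empt, fx$gene_models,
                                     fx$scores, overlap = "gene_body"),
                 "no genes")
  expect_null(r2$segment_profiles$gap)
})
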