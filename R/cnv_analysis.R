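# CNV annotation and the case-control battery: per-CNV score summaries,
# cohort t-tests, max-score-level contingency tests, the high-gene odds
# ratio, subgroup comparisons, pathogenicity regression and region reports.
#
# Coordinates are 0-based half-open internally (BED convention); readers
# convert 1-based input on load and reports print 1-based inclusive.

cnv_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Annotate CNVs with per-gene scores
#'
#' A gene is assigned to a CNV when the CNV overlaps at least one of its
#' exons by at least 1 bp (`overlap = "exon"`); the `"gene_body"` mode
#' treats each gene's full span as one interval for inputs without exon
#' models. For every CNV the overlapped genes' scores are summarized:
#' count, scored count, maximum level, median and mean percent (NA genes
#' excluded from the median/mean but counted in the gene total), and the
#' number of high-scoring genes. CNVs covering more than
#' `aneuploidy_frac` of a chromosome are excluded with a warning when
#' chromosome lengths are supplied.
#'
#' @param cnvs data.frame of CNV calls: `chrom`, `start`, `end` (0-based
#'   half-open) plus any of `cnv_type`, `cohort`, `sex`, `inheritance`,
#'   `classification`.
#' @param gene_models data.frame of intervals: `chrom`, `start`, `end`
#'   (0-based half-open), `symbol`; one row per exon (or per gene in
#'   `gene_body` mode).
#' @param scores Scored gene table from [score_genes()].
#' @param overlap `"exon"` (default) or `"gene_body"`; recorded in the
#'   output attribute `overlap_mode`.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp).
#' @param aneuploidy_frac Exclusion threshold as a fraction of chromosome
#'   length, default 0.9.
#' @return data.frame with one row per CNV: the input columns plus
#'   `size_bp`, `genes` (";"-joined symbols), `n_genes`, `scored_genes`,
#'   `max_level`, `median_percent`, `mean_percent`, `high_count`.
#' @export
annotate_cnvs <- function(cnvs, gene_models, scores,
                          overlap = c("exon", "gene_body"),
                          chrom_lengths = NULL, aneuploidy_frac = 0.9) {
  overlap <- match.arg(overlap)
  stopifnot(all(c("chrom", "start", "end") %in% names(cnvs)),
            all(c("chrom", "start", "end", "symbol") %in% names(gene_models)),
            all(c("symbol", "score", "high_scoring") %in% names(scores)))
  if (any(cnvs$end <= cnvs$start)) stop("CNV with end <= start")
  unknown <- setdiff(unique(cnvs$chrom), unique(gene_models$chrom))
  if (length(unknown))
    stop("CNV on chromosome absent from gene models: ",
         paste(unknown, collapse = ", "))

  if (!is.null(chrom_lengths)) {
    frac <- (cnvs$end - cnvs$start) / chrom_lengths[cnvs$chrom]
    drop <- !is.na(frac) & frac > aneuploidy_frac
    if (any(drop)) {
      warning(sum(drop), " CNV(s) covering > ", aneuploidy_frac * 100,
              "% of a chromosome excluded (aneuploidy guard)")
      cnvs <- cnvs[!drop, , drop = FALSE]
    }
  }

  if (overlap == "gene_body") {
    o <- order(gene_models$symbol)
    g <- gene_models[o, , drop = FALSE]
    first <- !duplicated(g$symbol)
    gm <- data.frame(chrom = g$chrom[first],
                     start = tapply(g$start, g$symbol, min)[g$symbol[first]],
                     end = tapply(g$end, g$symbol, max)[g$symbol[first]],
                     symbol = g$symbol[first])
  } else gm <- gene_models

  hits <- GenomicRanges::findOverlaps(cnv_granges(cnvs), cnv_granges(gm),
                                      minoverlap = 1L)
  q <- S4Vectors::queryHits(hits)
  sym <- gm$symbol[S4Vectors::subjectHits(hits)]
  keep <- !duplicated(paste(q, sym, sep = "\r"))
  q <- q[keep]; sym <- sym[keep]
  ord <- order(q, sym)
  q <- q[ord]; sym <- sym[ord]
  midx <- match(sym, scores$symbol)
  sc <- scores$score[midx]
  high <- !is.na(midx) & scores$high_scoring[midx]

  n <- nrow(cnvs)
  out <- cnvs
  out$size_bp <- cnvs$end - cnvs$start
  out$genes <- vapply(split(sym, factor(q, seq_len(n))),
                      paste, character(1), collapse = ";")
  out$n_genes <- tabulate(q, nbins = n)
  out$scored_genes <- tabulate(q[!is.na(sc)], nbins = n)
  grp <- factor(q[!is.na(sc)], seq_len(n))
  non_na <- sc[!is.na(sc)]
  mx <- suppressWarnings(vapply(split(non_na, grp), function(v)
    if (length(v)) max(v) else NA_integer_, numeric(1)))
  out$max_level <- as.integer(mx)
  out$median_percent <- vapply(split(20 * non_na, grp), score_median,
                               numeric(1))
  sums <- vapply(split(20 * non_na, grp), sum, numeric(1))
  out$mean_percent <- ifelse(out$scored_genes > 0,
                             sums / out$scored_genes, NA_real_)
  out$high_count <- tabulate(q[high], nbins = n)
  rownames(out) <- NULL
  attr(out, "overlap_mode") <- overlap
  out
}

#' Drop CNVs with no gene or only non-scored genes
#'
#' Mirrors the exclusion of CNVs that hit no exon of any gene and of CNVs
#' whose genes are all unscored (e.g. pseudogene-only CNVs).
#'
#' @param summaries Annotated CNV table from [annotate_cnvs()].
#' @param keep_na_only Keep NA-only CNVs (they stay for the max-score
#'   distribution, which has an NA level), default `FALSE`.
#' @return Filtered data.frame; attribute `n_dropped` records removals.
#' @export
filter_scored_cnvs <- function(summaries, keep_na_only = FALSE) {
  drop <- summaries$n_genes == 0
  if (!keep_na_only) drop <- drop | summaries$scored_genes == 0
  out <- summaries[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  out
}

welch_row <- function(test, stratum, x, y) {
  ok <- sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2
  if (!ok || stats::var(x, na.rm = TRUE) + stats::var(y, na.rm = TRUE) == 0) {
    return(data.frame(test = test, stratum = stratum,
                      case_mean = mean(x, na.rm = TRUE),
                      control_mean = mean(y, na.rm = TRUE),
                      statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  tt <- stats::t.test(x, y)        # Welch by default
  data.frame(test = test, stratum = stratum,
             case_mean = unname(tt$estimate[1]),
             control_mean = unname(tt$estimate[2]),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Compare case and control CNV cohorts
#'
#' Welch two-sided t-tests, stratified by loss/gain, for CNV size, total
#' gene content, and the mean and median per-CNV score percent; Bonferroni
#' significance at `0.05 / bonferroni_tests`.
#'
#' @param cases,controls Annotated CNV tables ([annotate_cnvs()]) with a
#'   `cnv_type` column.
#' @param bonferroni_tests Number of tests in the correction schedule,
#'   default 10 (five measures in two CNV classes).
#' @return Object of class `cohort_comparison`: data.frame of test rows
#'   (`test`, `stratum`, means, statistic, df, `p`, `significant`) with
#'   `bonferroni_alpha` attribute. Strata empty in either cohort are
#'   skipped with a warning.
#' @export
compare_cohorts <- function(cases, controls, bonferroni_tests = 10) {
  measures <- c(size_bp = "size_bp", gene_count = "n_genes",
                mean_percent = "mean_percent", median_percent = "median_percent")
  rows <- list()
  for (stratum in c("loss", "gain")) {
    cs <- cases[cases$cnv_type == stratum, , drop = FALSE]
    ct <- controls[controls$cnv_type == stratum, , drop = FALSE]
    if (!nrow(cs) || !nrow(ct)) {
      warning("stratum '", stratum, "' empty in one cohort; skipped")
      next
    }
    for (m in names(measures))
      rows[[paste(m, stratum)]] <-
        welch_row(m, stratum, cs[[measures[[m]]]], ct[[measures[[m]]]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  alpha <- 0.05 / bonferroni_tests
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "bonferroni_alpha") <- alpha
  class(out) <- c("cohort_comparison", "data.frame")
  out
}

#' Tabulate the highest-scoring gene per CNV by cohort
#'
#' @param cases,controls Annotated CNV tables with `cnv_type` and
#'   `max_level` columns; CNVs with no gene at all are excluded, NA-only
#'   CNVs populate the `"NA"` level.
#' @return data.frame of per-level counts: `stratum`, `level` (`"5"`..
#'   `"0"`, `"NA"`), `case_n`, `control_n`.
#' @export
max_score_table <- function(cases, controls) {
  lv <- function(df, stratum) {
    df <- df[df$cnv_type == stratum & df$n_genes > 0, , drop = FALSE]
    m <- factor(ifelse(is.na(df$max_level), "NA", as.character(df$max_level)),
                levels = c("5", "4", "3", "2", "1", "0", "NA"))
    table(m)
  }
  out <- do.call(rbind, lapply(c("loss", "gain"), function(s) {
    data.frame(stratum = s, level = c("5", "4", "3", "2", "1", "0", "NA"),
               case_n = as.integer(lv(cases, s)),
               control_n = as.integer(lv(controls, s)))
  }))
  rownames(out) <- NULL
  out
}

#' Test the max-score distribution between cohorts per level
#'
#' For every score level and stratum, a 2x2 of cohort by (max level equals
#' this level vs any other). Fisher's exact test is used when any observed
#' cell is at most 5 under the default rule (`"cell_le_5"`); the
#' `"expected"` rule switches on expected counts below 5 instead.
#'
#' @param counts Per-level count table from [max_score_table()] (columns
#'   `stratum`, `level`, `case_n`, `control_n`).
#' @param fisher_rule `"cell_le_5"` (default) or `"expected"`.
#' @param bonferroni_tests Correction schedule size, default 14 (seven
#'   levels in two CNV classes).
#' @return data.frame: counts plus `case_pct`, `control_pct`, `test`,
#'   `p`, `significant`; attribute `bonferroni_alpha`. Degenerate levels
#'   (zero in both cohorts) are skipped (NA p).
#' @export
max_score_tests <- function(counts, fisher_rule = c("cell_le_5", "expected"),
                            bonferroni_tests = 14) {
  fisher_rule <- match.arg(fisher_rule)
  alpha <- 0.05 / bonferroni_tests
  out <- counts
  out$case_pct <- out$control_pct <- out$p <- NA_real_
  out$test <- NA_character_
  for (s in unique(out$stratum)) {
    idx <- which(out$stratum == s)
    nc <- sum(out$case_n[idx]); nk <- sum(out$control_n[idx])
    out$case_pct[idx] <- 100 * out$case_n[idx] / nc
    out$control_pct[idx] <- 100 * out$control_n[idx] / nk
    for (i in idx) {
      tab <- matrix(c(out$case_n[i], nc - out$case_n[i],
                      out$control_n[i], nk - out$control_n[i]), 2, byrow = TRUE)
      if (sum(tab[, 1]) == 0) next  # level empty in both cohorts
      use_fisher <- if (fisher_rule == "cell_le_5") any(tab <= 5)
        else any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)
      if (use_fisher) {
        out$test[i] <- "fisher"; out$p[i] <- fisher_exact(tab)$p
      } else {
        out$test[i] <- "chi2"; out$p[i] <- chi2_test(tab)$p
      }
    }
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  attr(out, "bonferroni_alpha") <- alpha
  out
}

#' Odds ratio for CNVs carrying at least one high-scoring gene
#'
#' Pools loss and gain CNVs, excludes CNVs with no scored gene, and forms
#' the 2x2 of cohort by (one or more high-scoring genes vs none).
#'
#' @param cases,controls Annotated CNV tables.
#' @return [assoc_result()] with OR, Woolf CI and p.
#' @export
high_gene_or <- function(cases, controls) {
  cs <- filter_scored_cnvs(cases)
  ct <- filter_scored_cnvs(controls)
  tab <- matrix(c(sum(cs$high_count >= 1), sum(cs$high_count == 0),
                  sum(ct$high_count >= 1), sum(ct$high_count == 0)),
                2, byrow = TRUE)
  odds_ratio_2x2(tab)
}

#' Within-case subgroup comparison
#'
#' Welch two-sided t-tests on the mean percent, median percent and
#' high-scoring gene count between two subgroups of the case cohort:
#' male vs female, or inherited (maternal + paternal pooled) vs de novo.
#' CNVs with an unknown grouping value are excluded and counted.
#'
#' @param cases Annotated CNV table with `sex` or `inheritance` columns.
#' @param by `"sex"` or `"inheritance"`.
#' @return data.frame of test rows (as [compare_cohorts()], with
#'   `group1_mean` / `group2_mean`); attribute `n_excluded` counts CNVs
#'   with unknown grouping. Groups with fewer than 2 CNVs skip the test.
#' @export
subgroup_compare <- function(cases, by = c("sex", "inheritance")) {
  by <- match.arg(by)
  g <- if (by == "sex") {
    factor(ifelse(cases$sex %in% c("male", "female"), cases$sex, NA),
           levels = c("male", "female"))
  } else {
    factor(ifelse(cases$inheritance %in% c("maternal", "paternal"), "inherited",
                  ifelse(cases$inheritance == "de_novo", "de_novo", NA)),
           levels = c("inherited", "de_novo"))
  }
  n_excluded <- sum(is.na(g))
  rows <- lapply(c(mean_percent = "mean_percent",
                   median_percent = "median_percent",
                   high_count = "high_count"), function(col) {
    x <- cases[[col]][!is.na(g) & g == levels(g)[1]]
    y <- cases[[col]][!is.na(g) & g == levels(g)[2]]
    if (length(x) < 2 || length(y) < 2) {
      return(data.frame(group1_mean = mean(x, na.rm = TRUE),
                        group2_mean = mean(y, na.rm = TRUE),
                        statistic = NA_real_, df = NA_real_, p = NA_real_))
    }
    r <- welch_row("", "", x, y)
    data.frame(group1_mean = r$case_mean, group2_mean = r$control_mean,
               statistic = r$statistic, df = r$df, p = r$p)
  })
  out <- cbind(data.frame(measure = names(rows)), do.call(rbind, rows))
  rownames(out) <- NULL
  attr(out, "groups") <- levels(g)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Gene content versus CNV pathogenicity class
#'
#' Ordinary least squares of each gene-content measure on the 1-4
#' pathogenicity classification code (1 = population variant, 2 = likely
#' benign, 3 = VOUS, 4 = pathogenic/likely pathogenic), controlling for
#' CNV size.
#'
#' @param cases Annotated CNV table with a numeric `classification` column.
#' @param adjust_size Include `size_bp` as a covariate (default `TRUE`).
#' @return data.frame, one row per outcome (`high_count`, `low_count`,
#'   `nonscored_count`, `median_percent`): slope on classification, SE,
#'   t statistic, p.
#' @export
pathogenicity_regression <- function(cases, adjust_size = TRUE) {
  cl <- cases$classification
  keep <- !is.na(cl) & cl %in% 1:4
  d <- cases[keep, , drop = FALSE]
  if (length(unique(d$classification)) < 2L)
    stop("need at least two classification levels")
  d$low_count <- d$scored_genes - d$high_count
  d$nonscored_count <- d$n_genes - d$scored_genes
  fm <- if (adjust_size) "~ classification + size_bp" else "~ classification"
  rows <- lapply(c("high_count", "low_count", "nonscored_count",
                   "median_percent"), function(outc) {
    fit <- stats::lm(stats::as.formula(paste(outc, fm)), data = d)
    cf <- summary(fit)$coefficients["classification", ]
    data.frame(outcome = outc, slope = cf[["Estimate"]],
               se = cf[["Std. Error"]], t = cf[["t value"]],
               p = cf[["Pr(>|t|)"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score profile of a recurrent CNV region and its breakpoint segments
#'
#' Profiles the genes of a genomic region and of each breakpoint-delimited
#' segment within it: per-segment [profile_gene_set()] plus a per-gene
#' table (gene, score, high flag) for rendering.
#'
#' @param region List or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param segments data.frame of breakpoint segments (`name`, `chrom`,
#'   `start`, `end`), all within the region; may be empty.
#' @param gene_models Exon/gene interval table (as [annotate_cnvs()]).
#' @param scores Scored gene table.
#' @param overlap Overlap mode passed to [annotate_cnvs()].
#' @return List of class `region_report`: `region_profile`,
#'   `segment_profiles` (named list), `gene_table` (gene, segment(s),
#'   score, percent, high_scoring).
#' @export
region_report <- function(region, segments = NULL, gene_models, scores,
                          overlap = c("exon", "gene_body")) {
  overlap <- match.arg(overlap)
  region <- as.list(as.data.frame(region))
  segs <- if (is.null(segments) || !nrow(segments)) {
    data.frame(name = character(0), chrom = character(0),
               start = integer(0), end = integer(0))
  } else segments
  if (nrow(segs)) {
    inside <- segs$chrom == region$chrom & segs$start >= region$start &
      segs$end <= region$end
    if (!all(inside)) stop("segment outside region: ",
                           paste(segs$name[!inside], collapse = ", "))
  }
  iv <- rbind(data.frame(name = ".region", chrom = region$chrom,
                         start = region$start, end = region$end),
              segs[, c("name", "chrom", "start", "end")])
  ann <- annotate_cnvs(iv, gene_models, scores, overlap = overlap)
  genes_of <- function(i) {
    if (ann$n_genes[i] == 0) character(0)
    else strsplit(ann$genes[i], ";", fixed = TRUE)[[1]]
  }
  profs <- lapply(seq_len(nrow(ann)), function(i) {
    g <- genes_of(i)
    if (!length(g)) {
      warning("segment '", ann$name[i], "' covers no genes")
      return(NULL)
    }
    profile_gene_set(g, scores)
  })
  names(profs) <- ann$name
  rg <- genes_of(1)
  seg_of <- vapply(rg, function(sym) {
    hit <- vapply(seq_len(nrow(ann))[-1],
                  function(i) sym %in% genes_of(i), logical(1))
    paste(ann$name[-1][hit], collapse = ",")
  }, character(1))
  idx <- match(rg, scores$symbol)
  gene_table <- data.frame(
    symbol = rg, segment = unname(seg_of),
    score = scores$score[idx], percent = 20 * as.numeric(scores$score[idx]),
    high_scoring = !is.na(idx) & scores$high_scoring[idx])
  gene_table <- gene_table[order(-xtfrm(gene_table$score), gene_table$symbol,
                                 na.last = TRUE), ]
  rownames(gene_table) <- NULL
  structure(list(region_profile = profs[[1]],
                 segment_profiles = profs[-1],
                 gene_table = gene_table),
            class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat("Region: ")
  print(x$region_profile)
  for (nm in names(x$segment_profiles)) {
    cat("Segment", nm, ": ")
    if (is.null(x$segment_profiles[[nm]])) cat("(no genes)\n")
    else print(x$segment_profiles[[nm]])
  }
  invisible(x)
}
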