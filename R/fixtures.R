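# Packaged fixtures encoding published summary tables and two recurrent-CNV
# region gene lists. The region fixtures carry real gene symbols but
# synthetic coordinates and (beyond the published facts: total / scored /
# high-scoring counts and a few named genes) synthetic per-gene scores;
# their file names are marked `_synthetic` accordingly.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "neuroscore")
  if (p == "") stop("fixture file not installed: ", file)
  p
}

region_fixture <- function(file, region, segments) {
  genes <- utils::read.delim(fixture_path(file), stringsAsFactors = FALSE)
  scores <- data.frame(symbol = genes$symbol, score = genes$score,
                       percent = 20 * as.numeric(genes$score),
                       high_scoring = !is.na(genes$score) & genes$score >= 3)
  list(region = region, segments = segments,
       gene_models = genes[, c("chrom", "start", "end", "symbol")],
       scores = scores, genes = genes)
}

#' Load a packaged fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{`table2_counts`}{Per-score-level outcome counts of the
#'     19,601-gene universe (columns `level`, `total`, `cns`, `non_cns`,
#'     `no_phenotype`, `absent`); row and column sums are validated
#'     against the published totals on load.}
#'   \item{`table3_counts`}{Highest-scoring-gene-per-CNV counts by cohort
#'     and loss/gain stratum (`stratum`, `level`, `case_n`, `control_n`);
#'     cohort totals 835/2547/1357/1862 validated on load.}
#'   \item{`wbs_region`}{The 7q11.23 Williams-Beuren region gene list
#'     (25 genes, 15 scored, 6 high scoring); per-gene scores beyond the
#'     published facts are synthetic.}
#'   \item{`region_22q11`}{The 22q11.2 region (64 genes, 38 scored, 8 high
#'     scoring) with A-B / B-D / D-F breakpoint segments; per-gene scores
#'     beyond the published facts are synthetic.}
#' }
#'
#' @param name Fixture name.
#' @return `table2_counts` / `table3_counts`: a data.frame. Region
#'   fixtures: a list with `region`, `segments`, `gene_models`, `scores`.
#' @export
load_fixture <- function(name = c("table2_counts", "table3_counts",
                                  "wbs_region", "region_22q11")) {
  name <- match.arg(name)
  switch(name,
    table2_counts = {
      t2 <- utils::read.delim(fixture_path("table2_counts.tsv"))
      stopifnot(all(t2$cns + t2$non_cns + t2$no_phenotype == t2$total),
                sum(t2$total) == 18759, sum(t2$total) + 842 == 19601)
      t2
    },
    table3_counts = {
      t3 <- utils::read.delim(fixture_path("table3_counts.tsv"),
                              colClasses = c(level = "character"),
                              na.strings = "")
      tot <- tapply(t3$case_n, t3$stratum, sum)
      ctl <- tapply(t3$control_n, t3$stratum, sum)
      stopifnot(tot[["loss"]] == 835, tot[["gain"]] == 1357,
                ctl[["loss"]] == 2547, ctl[["gain"]] == 1862)
      t3
    },
    wbs_region = {
      fx <- region_fixture("wbs_region_synthetic.tsv",
        region = data.frame(chrom = "chr7", start = 72700000L,
                            end = 74200000L),
        segments = NULL)
      stopifnot(nrow(fx$genes) == 25, sum(!is.na(fx$genes$score)) == 15,
                sum(fx$scores$high_scoring) == 6)
      fx
    },
    region_22q11 = {
      fx <- region_fixture("region_22q11_synthetic.tsv",
        region = data.frame(chrom = "chr22", start = 18900000L,
                            end = 21900000L),
        segments = data.frame(
          name = c("A-B", "B-D", "D-F"), chrom = "chr22",
          start = c(18900000L, 20290000L, 21100000L),
          end = c(20290000L, 21100000L, 21900000L)))
      stopifnot(nrow(fx$genes) == 64, sum(!is.na(fx$genes$score)) == 38,
                sum(fx$scores$high_scoring) == 8)
      fx
    })
}

#' Expand a max-score count table into per-CNV rows
#'
#' Turns the per-level counts of the `table3_counts` fixture (or any
#' [max_score_table()] output) into one row per CNV with `cohort`,
#' `cnv_type`, `max_level`, and minimal gene-count columns, so the
#' CNV-level analyses ([high_gene_or()], [max_score_table()]) can run on
#' published counts. CNVs at the `"NA"` level get `scored_genes = 0`.
#'
#' @param counts data.frame with `stratum`, `level`, `case_n`, `control_n`.
#' @return data.frame of per-CNV rows.
#' @export
counts_to_summaries <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    lev <- counts$level[i]
    is_na_level <- is.na(lev) | lev == "NA"
    max_level <- if (is_na_level) NA_integer_ else as.integer(lev)
    scored <- if (is_na_level) 0L else 1L
    mk <- function(n, cohort) {
      if (n == 0) return(NULL)
      data.frame(cohort = cohort, cnv_type = counts$stratum[i],
                 max_level = max_level, n_genes = 1L, scored_genes = scored,
                 high_count = as.integer(scored & max_level >= 3))[rep(1, n), ]
    }
    rbind(mk(counts$case_n[i], "case"), mk(counts$control_n[i], "control"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
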