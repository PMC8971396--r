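# Synthetic-data generators: labeled gene universes with controllable
# per-metric effect sizes, synthetic gene maps, and case/control CNV
# cohorts with a configurable high-gene enrichment odds ratio. All
# generators are pure functions of their arguments plus the mandatory seed.

# marginal flag frequencies of the five retained metrics, from the
# published per-metric gene counts over the 19,601-gene universe
DEFAULT_METRIC_FREQ <- c(de_novo = 487, index = 4636, ccr99 = 1444,
                         gtex = 6069, gnomad_lof = 2896) / 19601

# final-model per-metric odds ratios used as generator truth
DEFAULT_METRIC_OR <- c(de_novo = 2.2, index = 1.9, ccr99 = 1.8,
                       gtex = 1.7, gnomad_lof = 1.4)

#' Simulate a labeled gene universe
#'
#' Draws correlated binary evidence flags by thresholding a latent
#' Gaussian copula (equicorrelation `rho`), assigns the binary CNS outcome
#' from a logistic model with the configured per-metric log-odds, and
#' back-fills raw metric values uniformly within the region consistent
#' with each flag so the binarizers round-trip exactly. A fraction
#' `missing_rate` of genes lose one randomly chosen raw metric value
#' (strict scoring then yields NA). Non-CNS genes are sub-labeled
#' `NON_CNS` / `NO_PHENOTYPE` / `ABSENT` at the configured proportions;
#' `non_cns_score0_or` optionally enriches zero-flag genes for the
#' `NON_CNS` label (negative-control structure).
#'
#' @param n_genes Number of genes; default 19601.
#' @param metric_freq Named marginal flag frequencies for the five final
#'   metrics (defaults: published per-metric counts / 19601).
#' @param metric_or Named per-metric outcome odds ratios (defaults: the
#'   final-model estimates 2.2, 1.9, 1.8, 1.7, 1.4).
#' @param extra_metrics Optional named list of additional candidate
#'   metrics, each `list(freq =, or =)` (e.g. null candidates with
#'   `or = 1`); emitted as flag columns only.
#' @param baseline_prev CNS prevalence among zero-flag genes; default
#'   0.0684 (the published zero-score stratum, 715/10461).
#' @param rho Latent equicorrelation between metric flags, default 0.
#' @param missing_rate Fraction of genes with one missing metric; default
#'   842/19601.
#' @param label_split Proportions of `NON_CNS` and `NO_PHENOTYPE` among
#'   non-CNS genes (remainder `ABSENT`); defaults from the published
#'   outcome-column totals.
#' @param non_cns_score0_or Odds multiplier for the `NON_CNS` label among
#'   zero-flag genes, default 1 (no enrichment).
#' @param seed Integer seed (mandatory).
#' @return data.frame: `symbol`, `ensembl_id`, raw metric columns
#'   (`oe_lof_upper`, `ccr_max_percentile`, `brain_tpm_median`,
#'   `denovo_count`, `index_flag`), any extra-metric flag columns,
#'   logical `cns`, and `outcome` in
#'   `{"CNS","NON_CNS","NO_PHENOTYPE","ABSENT"}`.
#' @export
simulate_genome <- function(n_genes = 19601,
                            metric_freq = DEFAULT_METRIC_FREQ,
                            metric_or = DEFAULT_METRIC_OR,
                            extra_metrics = NULL,
                            baseline_prev = 715 / 10461,
                            rho = 0,
                            missing_rate = 842 / 19601,
                            label_split = c(non_cns = 0.1334,
                                            no_phenotype = 0.8666 * 0.8665),
                            non_cns_score0_or = 1,
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(metric_freq > 0 & metric_freq < 1),
            baseline_prev > 0, baseline_prev < 1,
            all(metric_or > 0), missing_rate >= 0, missing_rate < 1)
  set.seed(as.integer(seed))

  freqs <- metric_freq[names(DEFAULT_METRIC_FREQ)]
  ors <- metric_or[names(DEFAULT_METRIC_OR)]
  extra_names <- names(extra_metrics) %||% character(0)
  all_freq <- c(freqs, vapply(extra_metrics, `[[`, numeric(1), "freq"))
  all_or <- c(ors, vapply(extra_metrics, `[[`, numeric(1), "or"))
  k <- length(all_freq)

  R <- matrix(rho, k, k); diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("infeasible correlation parameter rho = ", rho)
  Z <- MASS::mvrnorm(n_genes, mu = rep(0, k), Sigma = R)
  flags <- sweep(Z, 2, stats::qnorm(all_freq), "<")
  colnames(flags) <- c(names(freqs), extra_names)

  eta <- stats::qlogis(baseline_prev) + flags %*% log(all_or)
  cns <- stats::runif(n_genes) < stats::plogis(drop(eta))

  g <- data.frame(
    symbol = sprintf("GENE%05d", seq_len(n_genes)),
    ensembl_id = sprintf("ENSG%011d", seq_len(n_genes)),
    stringsAsFactors = FALSE)
  # raw values consistent with the flags, uniform within each flag's region
  f <- flags[, "gnomad_lof"]
  g$oe_lof_upper <- ifelse(f, stats::runif(n_genes, 0, 0.3449),
                           stats::runif(n_genes, 0.345, 2))
  f <- flags[, "ccr99"]
  g$ccr_max_percentile <- ifelse(f, stats::runif(n_genes, 99, 100),
                                 stats::runif(n_genes, 0, 98.99))
  f <- flags[, "gtex"]
  g$brain_tpm_median <- ifelse(f, stats::runif(n_genes, 10, 200),
                               stats::runif(n_genes, 0, 9.99))
  f <- flags[, "de_novo"]
  g$denovo_count <- ifelse(f, 10L + stats::rpois(n_genes, 4),
                           sample(0:9, n_genes, replace = TRUE))
  g$index_flag <- flags[, "index"]
  for (nm in extra_names) g[[nm]] <- flags[, nm]

  if (missing_rate > 0) {
    raw_cols <- c("denovo_count", "index_flag", "ccr_max_percentile",
                  "brain_tpm_median", "oe_lof_upper")
    hit <- which(stats::runif(n_genes) < missing_rate)
    which_col <- sample(raw_cols, length(hit), replace = TRUE)
    for (cc in raw_cols) g[[cc]][hit[which_col == cc]] <- NA
  }

  g$cns <- cns
  score0 <- rowSums(flags[, names(freqs), drop = FALSE]) == 0
  p_nc <- label_split[["non_cns"]]
  odds_nc <- p_nc / (1 - p_nc) * ifelse(score0, non_cns_score0_or, 1)
  p_nc_i <- odds_nc / (1 + odds_nc)
  u <- stats::runif(n_genes)
  rest_split <- label_split[["no_phenotype"]] / (1 - p_nc)
  g$outcome <- ifelse(cns, "CNS",
                 ifelse(u < p_nc_i, "NON_CNS",
                   ifelse((u - p_nc_i) / (1 - p_nc_i) < rest_split,
                          "NO_PHENOTYPE", "ABSENT")))
  g
}

#' Lay simulated genes on a synthetic gene map
#'
#' Places genes consecutively along chromosomes with intergenic gaps and
#' splits each gene body into exons, producing the exon-interval table the
#' CNV annotator consumes.
#'
#' @param symbols Character vector of gene symbols, in map order.
#' @param n_chrom Number of chromosomes, default 5.
#' @param seed Integer seed.
#' @param mean_exons,gene_span,gap Gene-structure parameters (counts/bp).
#' @return data.frame of exon intervals (`chrom`, `start`, `end`,
#'   `symbol`, 0-based half-open) with a `chrom_lengths` attribute.
#' @export
simulate_gene_map <- function(symbols, n_chrom = 5, seed,
                              mean_exons = 5, gene_span = 30000, gap = 20000) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  n <- length(symbols)
  chrom <- paste0("chr", rep_len(seq_len(n_chrom), n))
  chrom <- chrom[order(rep_len(seq_len(n_chrom), n))]
  rows <- vector("list", n)
  pos <- stats::setNames(rep(0L, n_chrom), paste0("chr", seq_len(n_chrom)))
  for (i in seq_len(n)) {
    ch <- chrom[i]
    span <- as.integer(stats::rexp(1, 1 / gene_span)) + 2000L
    gstart <- pos[[ch]] + as.integer(stats::rexp(1, 1 / gap)) + 1000L
    gend <- gstart + span
    n_ex <- 1L + stats::rpois(1, mean_exons - 1)
    cuts <- sort(sample(seq(gstart, gend - 100L, by = 100L), n_ex))
    rows[[i]] <- data.frame(chrom = ch, start = cuts,
                            end = pmin(cuts + 150L, gend),
                            symbol = symbols[i])
    pos[[ch]] <- gend
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "chrom_lengths") <- pos + gap
  out
}

#' Simulate case and control CNV cohorts
#'
#' Places CNVs as windows of consecutive genes on a gene map. Controls are
#' drawn from the natural window distribution; case CNVs are accepted or
#' rejected so that the odds of containing at least one high-scoring gene
#' equal `enrichment_or` times the natural odds (estimated from
#' `n_calibrate` sampled windows), giving the configured case-control
#' enrichment in expectation. Sex, inheritance and classification are
#' drawn from the configured mixes.
#'
#' @param scores Scored gene table ([score_genes()]) for the genome on the
#'   map.
#' @param gene_models Exon table from [simulate_gene_map()].
#' @param n_case,n_control Cohort sizes.
#' @param enrichment_or Target odds ratio for case CNVs containing a
#'   high-scoring gene, default 9.
#' @param loss_frac Fraction of loss (vs gain) CNVs, defaults matching the
#'   published cohort mix (cases 835/2192, controls 2547/4409).
#' @param mean_genes Mean number of genes per CNV, default 4.
#' @param sex_mix,inherit_mix,class_mix Category probabilities for the
#'   case annotations.
#' @param n_calibrate Windows sampled to estimate the natural high-gene
#'   rate, default 5000.
#' @param seed Integer seed.
#' @return List of two data.frames (`cases`, `controls`) of CNV records:
#'   `chrom`, `start`, `end`, `cnv_type`, `cohort`, `sex`, `inheritance`,
#'   `classification`.
#' @export
simulate_cnv_cohorts <- function(scores, gene_models, n_case = 2192,
                                 n_control = 4409, enrichment_or = 9,
                                 loss_frac = c(case = 835 / 2192,
                                               control = 2547 / 4409),
                                 mean_genes = 4,
                                 sex_mix = c(male = 0.79, female = 0.21),
                                 inherit_mix = c(maternal = 0.02,
                                                 paternal = 0.016,
                                                 de_novo = 0.015,
                                                 unknown = 0.949),
                                 class_mix = c(population = 0.886,
                                               likely_benign = 0.016,
                                               vous = 0.06,
                                               pathogenic = 0.038),
                                 n_calibrate = 5000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(enrichment_or > 0)
  set.seed(as.integer(seed))

  # per-gene spans in map order
  sym <- gene_models$symbol
  first <- !duplicated(sym)
  spans <- data.frame(
    chrom = gene_models$chrom[first],
    start = as.integer(tapply(gene_models$start, sym, min)[sym[first]]),
    end = as.integer(tapply(gene_models$end, sym, max)[sym[first]]),
    symbol = sym[first])
  spans <- spans[order(spans$chrom, spans$start), , drop = FALSE]
  high <- scores$high_scoring[match(spans$symbol, scores$symbol)]
  high[is.na(high)] <- FALSE
  n <- nrow(spans)

  # windows of consecutive genes, clipped at chromosome boundaries; a
  # cumulative count of high genes makes containment checks O(1)
  chrom_last <- stats::ave(seq_len(n), spans$chrom, FUN = max)
  cum0 <- c(0L, cumsum(high))   # cum0[i] = high genes before map position i
  draw_windows <- function(m) {
    i <- sample.int(n, m, replace = TRUE)
    k <- 1L + stats::rpois(m, mean_genes - 1)
    j <- pmin(i + k - 1L, chrom_last[i])
    cbind(i = i, j = j, has_high = (cum0[j + 1L] - cum0[i]) > 0L)
  }

  base_rate <- mean(draw_windows(n_calibrate)[, "has_high"])
  if ((base_rate == 0 || base_rate == 1) && enrichment_or != 1)
    stop("high-gene enrichment OR unreachable on this gene map ",
         "(natural rate ", base_rate, ")")

  target_rate <- function(or) {
    o <- or * base_rate / (1 - base_rate)
    o / (1 + o)
  }

  draw_cohort <- function(n_cnv, p_high) {
    want <- stats::runif(n_cnv) < p_high
    res_i <- res_j <- integer(n_cnv)
    open <- seq_len(n_cnv)
    while (length(open)) {
      w <- draw_windows(max(2L * length(open), 100L))
      for (h in c(TRUE, FALSE)) {
        slots <- open[want[open] == h]
        pool <- which(w[, "has_high"] == h)
        take <- seq_len(min(length(slots), length(pool)))
        res_i[slots[take]] <- w[pool[take], "i"]
        res_j[slots[take]] <- w[pool[take], "j"]
      }
      open <- open[res_i[open] == 0L]
    }
    pad1 <- sample(200:2000, n_cnv, replace = TRUE)
    pad2 <- sample(200:2000, n_cnv, replace = TRUE)
    data.frame(chrom = spans$chrom[res_i],
               start = pmax(0L, spans$start[res_i] - pad1),
               end = spans$end[res_j] + pad2)
  }

  cases <- draw_cohort(n_case, target_rate(enrichment_or))
  controls <- draw_cohort(n_control, base_rate)

  cases$cnv_type <- ifelse(stats::runif(n_case) < loss_frac[["case"]],
                           "loss", "gain")
  controls$cnv_type <- ifelse(stats::runif(n_control) < loss_frac[["control"]],
                              "loss", "gain")
  cases$cohort <- "case"; controls$cohort <- "control"
  cases$sex <- sample(names(sex_mix), n_case, TRUE, prob = sex_mix)
  controls$sex <- sample(names(sex_mix), n_control, TRUE, prob = sex_mix)
  cases$inheritance <- sample(names(inherit_mix), n_case, TRUE,
                              prob = inherit_mix)
  controls$inheritance <- "unknown"
  cls_code <- c(population = 1, likely_benign = 2, vous = 3, pathogenic = 4)
  cases$classification <- unname(cls_code[
    sample(names(class_mix), n_case, TRUE, prob = class_mix)])
  controls$classification <- 1
  rownames(cases) <- rownames(controls) <- NULL
  list(cases = cases, controls = controls)
}
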