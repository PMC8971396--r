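---
title: "Methods: the additive evidence score and its validation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the additive evidence score and its validation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroscore)
```

## The model

The score is an unweighted sum of five binary evidence flags per gene —
loss-of-function constraint, regional coding constraint at the 99th
percentile, brain expression, de novo variant burden, and an exon-level
index flag — giving an integer in 0–5, reported equivalently as a percent
of the possible points (one point = 20%). Genes meeting at least three
metrics are designated *high scoring*. The deliberate simplicity is the
point: each flag is auditable against its source table, the score is
reproducible by hand, and no fitted weight can drift as upstream
databases are updated.

The model's statistical justification is reconstructed, not assumed. Each
candidate flag is screened univariately against the binary CNS-phenotype
label by Pearson's chi-squared at $\alpha = 0.05$
(`screen_metrics()`); survivors enter a multiple logistic regression
that is pruned by backward elimination (`neuroscore_model()`):
first any flag whose variance inflation factor exceeds `vif_limit`
(default 5), then, iteratively with refitting, the flag with the largest
Wald p-value at or above $\alpha$. The additive score treats the
retained flags as exchangeable one-point contributions; the underlying
assumption — that the retained metrics carry comparable effect sizes on
the log-odds scale — is exactly what the coefficient table of the fitted
model lets a user check.

Assumptions worth stating explicitly: gene-level independence is assumed
by every contingency test (no correction for genomic clustering of
constrained genes); the outcome label is treated as fixed truth although
phenotype databases are incomplete; and the score's `NA` semantics are
strict — a gene missing any one metric is unscored rather than scored
optimistically (a lenient mode, `strict_na = FALSE`, treats missing as
`FALSE` and is off by default).

## Binarization cutoffs

All cutoffs are exposed as arguments with the published values as
defaults:

* `binarize_gnomad_lof()`: strictly below 0.345 (dimensionless o/e
  upper bound). The conventional "< 0.35" rule is applied with rounding
  from the thousandths place, hence the strict comparison at 0.345; a
  value of exactly 0.345 rounds to 0.35 and is not flagged.
* `binarize_ccr()`: at or above the 95th or 99th percentile
  (inclusive); only the 99th-percentile level feeds the final score.
* `binarize_gtex()`: median across the 13 brain-tissue median TPM
  values at or above 10 TPM (inclusive). The two-stage reduction
  (median of per-tissue medians) is used because the per-tissue medians
  are the distributed form of the source data; a pre-reduced scalar is
  accepted and compared directly.
* `binarize_denovo()`: at or above 10 collated de novo reports
  (inclusive). `dedup_denovo()` counts variant reports once per
  (subject, position, alternate allele) before thresholding, since the
  same event can be re-reported across overlapping study cohorts and no
  published deduplication rule exists; counting unique events is the
  conservative choice.
* `binarize_index()`: a gene is flagged when at least one of its exons
  is flagged; an empty exon list yields `FALSE`, not `NA`, because an
  assessed gene with no qualifying exon is a genuine negative.

## Statistical conventions

* **Fisher's exact test** uses the minimum-likelihood two-sided
  definition (the sum of hypergeometric point probabilities no larger
  than the observed table's), with a $1 + 10^{-7}$ relative guard when
  comparing point probabilities so ties are not lost to floating-point
  noise. The test suite checks it against full enumeration for every
  2×2 table with margins up to 12.
* **Odds ratios** are cross-product ratios with Woolf log-scale
  intervals ($\log \mathrm{OR} \pm z\sqrt{\sum 1/n_{ij}}$). When any
  cell is zero the Haldane–Anscombe correction adds 0.5 to every cell
  and the result notes it. This estimator equals the exponentiated
  coefficient of a one-predictor logistic regression, which the tests
  verify by an independent `glm` fit.
* **"Fisher when N ≤ 5"**: the cohort max-score battery switches from
  chi-squared to Fisher's exact test when any *observed* cell of the
  2×2 is at most 5 (`fisher_rule = "cell_le_5"`); an alternative rule
  on expected counts is available because the published phrasing admits
  both readings.
* **Bonferroni schedules** default to $0.05/10$ for the cohort t-tests
  (five measures in two CNV classes) and $0.05/14$ for the max-score
  battery (seven levels in two classes), both overridable.
* **t-tests** are Welch (unequal-variance) throughout; the pooled
  variant is not offered because the cohorts being compared differ in
  size and dispersion by construction.
* **Medians** of even-length sets are the mean of the two middle values
  everywhere (scores, percents, CNV summaries), so per-CNV and per-region
  summaries are reproducible from sorted score lists.
* **Minimum detectable OR** (`min_detectable_or()`) inverts a
  closed-form two-proportion power calculation (normal approximation,
  pooled variance under the null) by bisection; a Monte-Carlo test
  verifies the achieved power within 0.05. The construction behind the
  published value of this quantity is not fully specified, so the
  function takes all of its inputs explicitly rather than hard-coding a
  reconstruction.
* **Probability transform**: `probability_transform(or, baseline_odds)`
  returns $\frac{b \cdot \mathrm{OR}}{1 + b \cdot \mathrm{OR}}$, the
  logistic likelihood curve at the shifted log-odds. The baseline odds
  is an explicit argument because it is a property of the reference
  population, not of the model.

## Coordinates and CNV annotation

CNV and gene intervals are 0-based half-open internally (the BED
convention); the 1-based TSV dialect converts on load and reports print
1-based inclusive. A gene belongs to a CNV when the CNV overlaps at
least 1 bp of at least one exon (`overlap = "exon"`); the
`"gene_body"` mode exists for inputs without exon models and is recorded
in the output so downstream consumers can tell the two apart. CNVs
hitting no exon of any gene, and CNVs whose genes are all unscored
(pseudogene-like), are excluded from cohort analyses; CNVs covering more
than 90% of a chromosome are excluded as likely aneuploidies when
chromosome lengths are supplied. NA-scored genes count toward a CNV's
gene total but never toward its median, mean or maximum.

## The synthetic generators

`simulate_genome()` draws the five flags by thresholding a latent
Gaussian copula with equicorrelation `rho` (default 0, since no
published correlation structure exists for the metrics; the validation
tests that need populated upper score levels use `rho = 0.3–0.35`,
which is the regime the real metrics plausibly occupy given that
thousands of genes meet several of them). Marginal flag frequencies
default to the published per-metric gene counts over the 19,601-gene
universe, outcome labels come from a logistic model whose per-metric
odds ratios default to the published final-model estimates (2.2, 1.9,
1.8, 1.7, 1.4) with a zero-flag CNS prevalence of 715/10461, and a
missingness rate of 842/19601 reproduces the NA-scoring path. Raw
metric values are back-filled uniformly within the region consistent
with each flag, so the binarizers round-trip exactly and readers can be
tested end to end.

`simulate_cnv_cohorts()` places CNVs as windows of consecutive genes on
a synthetic map and accepts or rejects case windows so that the odds of
containing a high-scoring gene equal `enrichment_or` times the natural
odds (estimated from 5,000 sampled windows); controls follow the natural
window distribution. Cohort sizes and the loss/gain mix default to the
published cohort dimensions (2,192 case and 4,409 control CNVs).

What the generators do **not** emulate: linkage and genomic clustering
of constrained genes, realistic CNV size distributions tied to
recombination hotspots, recurrent CNVs at fixed breakpoints, shared
CNVs between related individuals, and phenotype-label noise. Passing
recovery tests therefore demonstrate that the estimators are correct
under the stated sampling model — not that the published effect sizes
are correct for real cohorts, which would require the original
proprietary call sets.

## Problem sizes used in validation

The parameter-recovery tests fit 100 replicate genomes of 15,000 genes
(backward-elimination retention), 100 replicate CNV cohorts at the
published cohort scale (interval coverage of a configured enrichment OR
of 9), and 20–40 replicates for the smaller-effect recoveries
(negative-control OR, subgroup shifts, phenotype-class ORs). These sizes
were chosen to put each check's pass probability well above its
threshold under the generating model while keeping the full suite
runnable on a laptop in a couple of minutes.

## Fixtures

Two kinds of fixtures ship with the package. The count tables
(`table2_counts`, `table3_counts`) transcribe published per-level
summary counts and are validated against their printed row and column
totals on every load. The region fixtures (`wbs_region`,
`region_22q11`) carry real gene symbols for the 7q11.23 and 22q11.2
recurrent-CNV regions, but synthetic coordinates and — beyond the
published facts (gene totals, scored and high-scoring counts, the
identities of the named high-scoring genes, one published per-gene
score) — synthetic per-gene scores; their file names are suffixed
`_synthetic` and nothing in the test suite asserts an unpublished
per-gene value.

## Known limitations

Scores recomputed from flags are the only trusted form; score columns in
input files are ignored rather than reconciled. The per-score-level odds
ratios of the published model are not reproducible from the published
count table alone (the fitting snapshot of the phenotype database
predates the printed counts), so the package validates its per-level OR
machinery by parameter recovery on synthetic genomes instead, and the
outcome universe for those ORs is configurable. The ortholog analysis
implements unadjusted 2×2 class ORs; no adjustment for the number of
phenotypes per gene is attempted. The harmonizer resolves symbols
through explicit alias tables only — it does not guess at similarity —
and reports conflicts rather than merging them.
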