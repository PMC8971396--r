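# neuroscore

An R package for prioritizing candidate central-nervous-system (CNS)
disease genes with an additive multi-omic evidence score, and for
validating such a score against case–control copy-number-variant (CNV)
cohorts and mouse-ortholog phenotype data.

## The problem and the model

Most genes have never been linked to a human phenotype, yet clinical CNVs
routinely delete or duplicate dozens of them. The package implements a
deliberately simple, transparent prioritization model: a gene earns **one
point for each of five binary evidence metrics** it meets, giving a score
of 0–5 (equivalently 0–100% in 20% steps):

| metric | cutoff | evidence captured |
|---|---|---|
| `gnomad_lof` | o/e LOF upper bound < 0.345 | intolerance to loss-of-function variation |
| `ccr99` | ≥ 1 constrained coding region at ≥ 99th percentile | regional coding constraint |
| `gtex` | median brain expression ≥ 10 TPM across 13 brain tissues | brain expression |
| `de_novo` | ≥ 10 collated de novo variants in neurodevelopmental cohorts | de novo burden |
| `index` | ≥ 1 exon both brain-expressed and depleted of rare variation | exon-level index |

A gene missing any metric scores `NA`; a gene with score ≥ 3 is **high
scoring**. The metric set itself is validated by a univariate chi-squared
screen followed by multiple logistic regression with backward elimination
(Wald tests, collinearity pruning), exposed in the classic R modelling
idiom as `neuroscore_model()` with `print`/`summary`/`coef`/`predict`
methods. For a score level \(s\) with \(n_{s1}\) CNS-associated and
\(n_{s0}\) other genes, enrichment over the zero-score reference is the
cross-product odds ratio \(\mathrm{OR}_s = (n_{s1} n_{00}) / (n_{s0}
n_{01})\) with a Woolf log-scale confidence interval — the same 2×2
machinery drives the CNV burden tests, the gene-set enrichment test and
the mouse-phenotype enrichment.

Everything downstream of the score is included: exon-aware CNV
annotation, cohort t-tests and max-score contingency batteries with
Bonferroni schedules, subgroup and pathogenicity regressions,
recurrent-region reports, 1:1 human–mouse ortholog filtering with
27-phenotype enrichment, and seeded synthetic-data generators
(`simulate_genome()`, `simulate_cnv_cohorts()`) so every stage is
testable without external downloads.

## Worked example

```r
library(neuroscore)

# a seeded synthetic genome with the published metric frequencies and
# final-model odds ratios as generator truth
genes  <- simulate_genome(n_genes = 19601, seed = 1)
scores <- score_genes(compute_metric_flags(genes))
table(scores$score, useNA = "ifany")
#>    0    1    2    3    4    5 <NA>
#> 7571 7970 2796  443   25    1  795

fit <- neuroscore_model(
  cns ~ de_novo + index + ccr99 + gtex + gnomad_lof, scores)
fit
#> Additive evidence model (logistic, backward elimination)
#>   n = 18806  retained: 5  dropped: 0
#>   metric       OR         [lo, hi]  p
#>   de_novo        1.94  [ 1.53,  2.47]  4e-08
#>   index          1.85  [ 1.68,  2.05]  1.1e-33
#>   ccr99          1.77  [ 1.52,  2.05]  9.3e-14
#>   gtex           1.77  [ 1.61,  1.95]  5.1e-32
#>   gnomad_lof     1.44  [ 1.27,  1.62]  4.9e-09
```

The five retained coefficients recover the generating odds ratios (2.2,
1.9, 1.8, 1.7, 1.4) within sampling error. On the packaged cohort-count
fixture, the CNV-level analysis reproduces the published burden result:

```r
t3 <- load_fixture("table3_counts")
s3 <- counts_to_summaries(t3)
high_gene_or(s3[s3$cohort == "case", ], s3[s3$cohort == "control", ])
#> <or_2x2>, p = 3.32e-109, OR = 9.32 [7.41, 11.7]
```

i.e. case CNVs are ~9.3 times more likely than population-control CNVs to
contain at least one high-scoring gene. Region profiling works the same
way (`region_report()`, see `load_fixture("wbs_region")` for the 7q11.23
Williams–Beuren region: 25 genes, 15 scored, 6 high scoring).

A thin CLI over the same functions is installed at
`inst/cli/neuroscore.R` (subcommands `score-genes`, `fit-model`,
`score-cnvs`, `compare-cohorts`, `region-report`, `mouse-enrich`,
`simulate`).

## Vignette

`vignettes/neuroscore-methods.Rmd` describes the model and its
assumptions, the binarization cutoffs, the statistical conventions (Fisher
rule, Haldane–Anscombe correction, Woolf intervals, Bonferroni schedules),
what the synthetic generators do and do not emulate, and known
limitations.
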