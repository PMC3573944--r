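# grsrisk

Construction and evaluation of multifactorial genetic risk models from
candidate SNPs in case-control studies.

Genome-wide association studies yield risk loci whose individual effects
are too small for prediction (per-allele odds ratios 1.1–1.2). `grsrisk`
implements the standard workflow for asking whether a handful of such loci,
combined into a **genetic risk score (GRS)** and joined with an exposure
such as smoking, adds useful discrimination to a risk model — the design
used in candidate-SNP lung-cancer risk studies, but applicable to any
binary-outcome panel of biallelic markers.

## The models

**Per-SNP association.** For each locus: Hardy–Weinberg equilibrium
(chi-square, 1 df, with an exact option), the crude allelic odds ratio from
the collapsed 2×2 allele table with Woolf confidence interval
`exp(ln OR ± 1.96 √(Σ 1/cell))`, pairwise linkage disequilibrium D′ via EM
haplotype estimation, and the liability-threshold variance explained

> V = 2p(1−p) β²,  β = ln OR

interpreted as the fraction of unit liability variance attributable to a
locus with risk-allele frequency *p*.

**Risk scores.** The count score (cGRS) is the sum of risk-allele dosages.
The weighted score (wGRS) is multiplicative: with
`u = (1−p)² + 2p(1−p)·OR + p²·OR²` the population-average relative risk at
a locus, genotypes with dosage 0/1/2 get weights `1/u, OR/u, OR²/u`
(HWE-weighted mean exactly 1), and `wGRS = Π SNP_k`; missing genotypes
contribute a factor of 1. wGRS is categorised into deciles of the control
distribution.

**Risk model and evaluation.** Logistic regression of status on the wGRS
decile rank (0–9) and ordinal smoking (0/1/2), exposed as a relative-odds
calculator `exp(b0 + b1·decile + b2·smoking)`; rank-based AUC
(Mann–Whitney, ties = ½) with bootstrap-percentile CIs; paired-bootstrap
(or DeLong) AUC comparison; Hosmer–Lemeshow calibration; Harrell bootstrap
optimism correction; 75/25 split validation; Youden-cutoff confusion
metrics. A seeded simulator generates cohorts under the log-additive odds
model with case-control ascertainment by rejection sampling, and
`expand_counts()` turns printed contingency tables into individual-level
records.

## Worked example

```r
library(grsrisk)

# a cohort with the default four-SNP panel at study scale
cohort <- simulate_cohort(sim_config(seed = 42))
assoc_table(cohort)[, c("snp_id", "oratio", "var_explained_pct")]
#>      snp_id oratio var_explained_pct
#> 1 rs2736100   1.17             1.154
#> 2  rs402710   1.13             0.649
#> 3 rs4083914   1.10             0.227
#> 4 rs4488809   1.19             1.583

scores <- score_cohort(cohort, snps = default_snp_panel())
fit_risk_model(scores)
#> Logistic risk model (status ~ wGRS decile + smoking)
#>              coef     OR ci_low ci_high p
#> intercept -0.9580 0.3836 0.3378  0.4357 0
#> wgrs       0.0639 1.0660 1.0452  1.0872 0
#> smoking    0.5000 1.6488 1.5457  1.7588 0

# discrimination of smoking alone, from printed three-level counts
sm <- expand_counts(data.frame(label = c("never", "light", "heavy"),
                               cases = c(801, 416, 1066),
                               controls = c(1517, 542, 726)),
                    category = "smoking", values = 0:2)
auc_rank(sm$smoking, sm$status)
#> AUC = 0.619  [2283 cases / 2785 controls]

auc_rank(scores$wgrs, scores$status)
#> AUC = 0.554  [2283 cases / 2785 controls]

# relative odds for a top-decile heavy smoker under published coefficients
relative_risk(c(-0.9372, 0.0610, 0.5142), wgrs_decile = 9, smoking = 2)
#> [1] 1.89686
```

The per-SNP odds ratios recover the generating values (1.18/1.10/1.15/1.21),
the fitted slopes sit close to the published ones (0.0610 for wGRS decile,
0.5142 per smoking level), smoking alone discriminates with AUC 0.619, and
the wGRS alone reaches ≈0.55 — genetic information at this panel size is
real but modest.

## End-to-end pipeline and CLI

```r
run_pipeline(pipeline_config(snps = default_snp_panel(), seed = 1),
             "cohort.tsv", "out/")
```

writes `assoc_table.tsv`, `snp_weights.tsv`, `scores.tsv`, three
category-OR tables, `model_fit.txt`, `eval_report.txt` and `run_log.txt`,
each stamped with a config hash and seed; reruns are byte-identical. The
same steps are scriptable via `grsrisk::grs_cli()` with subcommands
`simulate`, `expand-counts`, `assoc`, `score`, `run`, and common flags
`--config`, `--cohort`, `--seed`, `--out`.

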