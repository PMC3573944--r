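---
title: "Methods: genetic risk scores, the combined risk model, and how they are validated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic risk scores, the combined risk model, and how they are validated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsrisk)
```

## The problem

A case-control study genotypes a handful of candidate susceptibility SNPs —
loci with per-allele odds ratios around 1.1–1.2, individually useless for
prediction — and asks three questions: are the loci associated in this
population; how much of the heritable liability do they explain; and does a
combined genetic risk score add discrimination to a model built on an
established exposure (here, smoking). `grsrisk` implements that workflow
end to end, together with the simulation machinery needed to test it.

## Models and assumptions

### Log-additive genotype risk

Each biallelic locus is coded by its risk-allele dosage $d \in \{0,1,2\}$.
The log-additive model assigns genotype relative risks $1, \mathrm{OR},
\mathrm{OR}^2$. All downstream machinery (simulation, weighting, the
liability calculation) assumes this model; dominance is out of scope.

### The weighted score and its normalisation

With risk-allele frequency $p$ and Hardy-Weinberg genotype proportions, the
population-average relative risk at a locus is
$$u = (1-p)^2 + 2p(1-p)\,\mathrm{OR} + p^2\,\mathrm{OR}^2 .$$
`snp_genotype_scores()` divides the genotype relative risks by $u$, and
`compute_wgrs()` multiplies the per-locus weights across the panel. In the
default `"normalized"` mode the dosage-2 weight is $\mathrm{OR}^2/u$, so the
HWE-weighted mean weight at every locus is exactly 1 and the population mean
wGRS converges to 1 — which is what makes "missing genotype contributes a
factor of 1" the neutral imputation. A `"literal"` mode with
$\mathrm{OR}^2/u^2$ for dosage 2 is also provided, because that variant
scaling appears in print; its population mean falls below 1 whenever
$\mathrm{OR} \neq 1$, which is why it is not the default. Quantities used in
acceptance checks (cGRS bands, decile categories) are insensitive to the
choice because they depend on the score only through ranks within a locus
pattern.

A missing genotype contributes 0 risk alleles to the count score cGRS
(keeping it integer-valued); an alternative `missing = "expected"` imputes
the HWE expectation $2p$. With >99% genotyping rates the choice is
immaterial, but both are exposed.

### Liability-scale variance explained

Under a liability-threshold model with additive allelic effect
$\beta = \ln \mathrm{OR}$ on a unit-variance liability, a locus explains
$2p(1-p)\beta^2$ of the liability variance (`variance_explained()`,
reported as percent). For the default panel this gives 1.33%, 0.40%, 0.47%
and 1.81% — about 4% in total, the quantitative statement of "individually
modest loci". Note the fourth value: recomputing from inputs rounded to two
decimals gives 1.81%, while 1.82% circulates from unrounded inputs; the
package reports what the formula gives.

### The combined risk model

`fit_risk_model()` is a maximum-likelihood logistic regression of status on
the wGRS **decile rank** (0–9) and ordinal smoking (0 = never, 1 = light,
2 = heavy). The decile-rank coding (rather than raw wGRS units) is the
default because published per-unit effects of roughly $e^{9b_1} \approx
1.7$ from lowest to highest decile are consistent with rank coding and not
with raw multiplicative units; `covariate = "wgrs"` switches to raw units.
Smoking as ordinal 0/1/2 is likewise supported by the observed
heavy-versus-never odds ratio matching $e^{2 b_2}$. Age and gender, being
null in the motivating design, are not default covariates but can be added
via `extra =`.

Deciles are computed on the **control** distribution by default: controls
approximate the source population under ascertainment, and the decile
labels then read "relative to the background distribution". Whether a
given published analysis used controls or the pooled sample is usually
unstated; `decile_reference = "pooled"` is provided, and the two differ
visibly because the wGRS takes finitely many values, making categories
uneven either way (ties at a cut point always go to the upper category, so
the top category genuinely means "$\ge Q_{90}$").

## The synthetic cohort generator

`simulate_cohort()` draws population individuals with independent HWE
genotypes per SNP and smoking independent of genotype, assigns disease by
$\operatorname{logit}^{-1}(\alpha + \sum_k \beta_k d_k + \beta_s s)$, and
collects the first `n_cases` cases and `n_controls` controls — rejection
sampling, i.e. case-control ascertainment from a defined population. The
intercept $\alpha$ is solved by exact enumeration over all
genotype-by-smoking cells so the marginal disease probability equals the
configured prevalence.

Defaults state the emulated world: the four-SNP panel with frequencies
0.41/0.68/0.14/0.47 and odds ratios 1.18/1.10/1.15/1.21; 2,283 cases and
2,785 controls; control smoking distribution 54.5/19.5/26.1% with per-level
OR 1.67; genotype missingness 0.5% completely at random. The population
prevalence is not identified by a case-control design; 0.01 is the
documented assumption, chosen so the rare-disease approximation holds and
odds ratios read as relative risks. One integer seed governs every draw.

What the generator does **not** emulate: linkage disequilibrium between
panel SNPs (the motivating panel is effectively independent, D′ ≈ 0.02),
gene-environment correlation, continuous pack-year smoking, genotyping
error, and population stratification. A green simulation-based test
therefore establishes internal consistency of estimator and generator — not
robustness to those real-data features.

## Evaluation machinery and numerical choices

- **AUC** (`auc_rank()`) is the Mann–Whitney probability with ties counted
  one half, computed from midranks; its confidence interval is a seeded
  bootstrap percentile interval (B = 1000 by default — published
  asymmetric intervals suggest percentile rather than Wald). The ROC curve
  collapses tied scores into single steps, so trapezoidal integration
  reproduces the rank AUC to 1e-10.
- **AUC comparison** (`compare_auc()`) uses a paired bootstrap over
  subjects by default (no method is typically named in print); DeLong's
  asymptotic test is available as an option. The two-sided p-value is
  `2 min(P(Δ* ≤ 0), P(Δ* ≥ 0))`, capped at 1.
- **Rank invariance caveat**: AUC is invariant under strictly monotone
  transforms mathematically; in double precision a transform like `exp()`
  can collapse scores that differ near machine epsilon into exact ties,
  shifting the statistic in the fourth decimal at n ≈ 5000. Tests assert
  affine invariance exactly and `exp` invariance to 1e-3.
- **Hosmer–Lemeshow** (`hosmer_lemeshow()`) bins by fitted-probability
  deciles and uses $\sum (O-E)^2 / (E(1-E/n_g))$ on $g-2$ df, merging
  degenerate bins with a warning. A published "Hosmer-Lemeshow 0.154" is
  read as the p-value — a statistic of 0.154 on 8 df would be implausibly
  small.
- **Optimism correction** (`bootstrap_optimism()`) is Harrell's procedure:
  refit on each resample, optimism = mean(AUC on resample − AUC on
  original), corrected = apparent − optimism. Replicates whose refit fails
  are dropped and counted; more than 10% failures aborts.
- **Split validation** (`split_validate()`) refits on a seeded 75% training
  split and reports the c statistic on both parts; a class-empty split is
  redrawn once, then fails. The Youden cutoff is chosen on the training
  scores (the natural reading when a cutoff is then "assessed" on a test
  set), with ties on sensitivity+specificity broken toward higher
  specificity.
- **Association estimator**: the per-SNP odds ratio is the crude allelic
  2×2 cross-product with Woolf CI — this choice reproduces published
  category tables at two decimals, and a log-additive logistic per-SNP fit
  is available as a cross-check (`assoc_table(logistic_check = TRUE)`).
  Zero cells trigger the Haldane-Anscombe 0.5 correction, flagged. The HWE
  test is the asymptotic chi-square by default (borderline published
  p-values of exactly 0.05 indicate chi-square rather than exact); the
  Levene-Haldane exact test is the `method = "exact"` option.
- **D′** is estimated from unphased genotypes by EM over the
  double-heterozygote phase (tolerance 1e-12). EM on unphased data carries
  slightly more variance than phased haplotype counting; the two agree
  exactly only when no double heterozygotes occur.

## Determinism and the pipeline

Every stochastic operation takes an explicit seed and restores the caller's
RNG state. `run_pipeline()` writes its artifacts with fixed numeric
formatting and stamps each with an FNV-1a hash of the configuration plus
the seed, so a rerun with identical inputs is byte-identical; the run log
records the switches actually taken (wGRS mode, decile policy, CI method,
bootstrap size).

## Known limitations

Candidate-panel scale only (no VCF/PLINK input, no imputation, no
genome-wide data structures); no absolute-risk projection anchored to
incidence; no external-cohort validation machinery; no LD-aware weighting.
The simulator's independence assumptions above bound what its tests can
establish.
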