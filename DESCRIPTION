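Package: grsrisk
Title: Genetic Risk Scores and Risk-Model Evaluation for Candidate-SNP
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("GRS", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of multifactorial genetic risk
    models from candidate single-nucleotide polymorphisms (SNPs) in
    case-control data.  Implements per-SNP quality control and association
    (Hardy-Weinberg equilibrium, allelic odds ratios with Woolf confidence
    intervals, pairwise linkage disequilibrium via EM haplotype estimation,
    liability-threshold variance explained), count-based (cGRS) and
    weighted multiplicative (wGRS) genetic risk scores with
    population-average normalisation and decile categorisation, combined
    GRS-by-smoking logistic risk models, and discrimination, calibration
    and internal-validation machinery (rank-based AUC with bootstrap
    confidence intervals, paired AUC comparison, Hosmer-Lemeshow
    calibration, Harrell bootstrap optimism correction, split-sample
    validation, Youden cutoff metrics).  A seeded cohort simulator
    generates case-control data under a log-additive odds model for
    testing and power exploration, and printed contingency tables can be
    expanded into individual-level records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
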