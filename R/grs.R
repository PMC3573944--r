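#' Population-average relative risk at a locus
#'
#' Under the log-additive model the genotypes with 0, 1 and 2 copies of the
#' risk allele carry relative risks 1, OR and OR^2.  With risk-allele
#' frequency `p` and Hardy-Weinberg genotype proportions, the average
#' relative risk in the population is
#' `u = (1-p)^2 + 2p(1-p) OR + p^2 OR^2`.
#'
#' @param p Risk-allele frequency in \[0, 1\].
#' @param oratio Per-allele odds ratio (> 0).
#' @return The scalar `u` (>= min(1, OR^2)).
#' @examples
#' average_relative_risk(0.41, 1.18)  # 1.1530
#' @export
average_relative_risk <- function(p, oratio) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_bad_arg("p must lie in [0, 1]")
  if (!is.numeric(oratio) || any(is.na(oratio)) || any(oratio <= 0))
    stop_bad_arg("oratio must be > 0")
  (1 - p)^2 + 2 * p * (1 - p) * oratio + p^2 * oratio^2
}

#' Genotype-level weights for the weighted genetic risk score
#'
#' Returns the adjusted risk value for dosages 0, 1 and 2 at one locus.  In
#' `"normalized"` mode (the default) the weights are `1/u, OR/u, OR^2/u`,
#' whose Hardy-Weinberg-weighted population mean is exactly 1 — the property
#' the average-relative-risk normalisation is meant to deliver.  `"literal"`
#' mode instead uses `OR^2/u^2` for the homozygous risk genotype, an
#' alternative scaling sometimes quoted; its population mean is slightly
#' below 1 whenever OR != 1.  See the methods vignette for why
#' `"normalized"` is the default.
#'
#' @inheritParams average_relative_risk
#' @param mode `"normalized"` or `"literal"`.
#' @return A list with `u` and `genotype_scores` (length-3 numeric, dosage
#'   0/1/2 order).
#' @examples
#' snp_genotype_scores(0.41, 1.18)$genotype_scores  # 0.8673 1.0234 1.2076
#' @export
snp_genotype_scores <- function(p, oratio, mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  u <- average_relative_risk(p, oratio)
  s2 <- if (mode == "normalized") oratio^2 / u else oratio^2 / u^2
  list(u = u, genotype_scores = c(1 / u, oratio / u, s2), mode = mode)
}

#' Weight table for a SNP panel
#'
#' @param snps SNP panel (see [snp_panel()]).
#' @inheritParams snp_genotype_scores
#' @return Data frame with one row per SNP: `snp_id`, `u`, `s0`, `s1`, `s2`
#'   (scores for dosage 0/1/2) and `mode`.
#' @export
snp_weights <- function(snps, mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    w <- snp_genotype_scores(snps$p[i], snps$oratio[i], mode)
    data.frame(snp_id = snps$snp_id[i], u = w$u,
               s0 = w$genotype_scores[1], s1 = w$genotype_scores[2],
               s2 = w$genotype_scores[3], mode = mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Weighted genetic risk score (wGRS)
#'
#' The wGRS of a subject is the product across SNPs of the genotype score
#' matching the subject's dosage; a missing genotype contributes a factor of
#' exactly 1 (the population-average relative risk in normalised units).
#'
#' @param cohort A `grs_cohort`.
#' @param weights Weight table from [snp_weights()]; must cover every SNP
#'   column of the cohort.
#' @return Numeric vector of per-subject scores (> 0), in cohort row order.
#' @export
compute_wgrs <- function(cohort, weights) {
  snp_ids <- attr(cohort, "snp_ids")
  missing_w <- setdiff(snp_ids, weights$snp_id)
  if (length(missing_w))
    stop_bad_arg("no weights for SNP(s): %s", paste(missing_w, collapse = ", "))
  validate_cohort(cohort)
  dos <- dosage_matrix(cohort)
  logscore <- numeric(nrow(dos))
  for (s in snp_ids) {
    w <- weights[weights$snp_id == s, ]
    ls <- log(c(w$s0, w$s1, w$s2))
    d <- dos[, s]
    contrib <- ifelse(is.na(d), 0, ls[d + 1L])
    logscore <- logscore + contrib
  }
  unname(exp(logscore))
}

#' Count genetic risk score (cGRS)
#'
#' Sum of risk-allele dosages over the panel.  A missing genotype
#' contributes 0 risk alleles by default (`missing = "zero"`, keeping the
#' score an integer); `missing = "expected"` imputes the Hardy-Weinberg
#' expectation `2p` instead, which requires `freqs`.
#'
#' @param cohort A `grs_cohort`.
#' @param missing `"zero"` or `"expected"`.
#' @param freqs Named risk-allele frequencies (one per SNP column), needed
#'   only for `missing = "expected"`.
#' @return Numeric vector of per-subject counts.
#' @export
compute_cgrs <- function(cohort, missing = c("zero", "expected"), freqs = NULL) {
  missing <- match.arg(missing)
  validate_cohort(cohort)
  dos <- dosage_matrix(cohort)
  if (missing == "zero") {
    rowSums(dos, na.rm = TRUE)
  } else {
    snp_ids <- attr(cohort, "snp_ids")
    if (is.null(freqs) || !all(snp_ids %in% names(freqs)))
      stop_bad_arg("missing = 'expected' needs a named freqs entry per SNP")
    imp <- dos
    for (s in snp_ids) imp[is.na(imp[, s]), s] <- 2 * freqs[[s]]
    rowSums(imp)
  }
}

#' Band a count GRS into the conventional reporting categories
#'
#' Categories 0-1, 2, 3, 4, 5 and >=6 risk alleles, as used when tabulating
#' cGRS against disease status for a four-SNP panel.
#'
#' @param cgrs Numeric vector of allele counts.
#' @return Ordered factor with levels `0-1, 2, 3, 4, 5, >=6`.
#' @export
cgrs_band <- function(cgrs) {
  lv <- c("0-1", "2", "3", "4", "5", ">=6")
  idx <- pmin(pmax(floor(cgrs), 1), 6)  # 0 and 1 collapse; 6+ collapses
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Decile categories relative to a reference distribution
#'
#' Cut points are the 10th-90th percentiles of the reference wGRS
#' distribution (by default the control group).  A score below Q10 falls in
#' category 0, at or above Q90 in category 9; a score exactly at a cut point
#' goes to the upper category, so category 9 always means ">= Q90".  Because
#' the wGRS takes finitely many values, ties can make categories markedly
#' uneven.
#'
#' @param scores Numeric scores to categorise.
#' @param reference Non-empty numeric reference distribution defining the
#'   cut points.
#' @return Integer vector in 0..9, same length as `scores`.
#' @export
decile_categories <- function(scores, reference) {
  if (length(reference) == 0L || all(is.na(reference)))
    stop_bad_arg("reference distribution is empty")
  cuts <- stats::quantile(reference, probs = seq(0.1, 0.9, by = 0.1),
                          na.rm = TRUE, names = FALSE, type = 7)
  findInterval(scores, cuts)  # ties go to the upper category
}

#' Score a cohort: cGRS, wGRS and decile categories in one pass
#'
#' @param cohort A `grs_cohort`.
#' @param snps SNP panel supplying frequencies and odds ratios for the
#'   weights; defaults to estimating both from the cohort's control group
#'   (control allele frequency, allelic OR), which is how a study weights
#'   its own score.
#' @param mode wGRS weighting mode, see [snp_genotype_scores()].
#' @param decile_reference `"controls"` (default) or `"pooled"`: which
#'   subjects define the decile cut points.
#' @return A `data.frame` (class `grs_scores`) with columns `subject_id`,
#'   `status`, `smoking`, `cgrs`, `cgrs_band`, `wgrs`, `wgrs_decile`, plus
#'   the weight table in attribute `weights`.
#' @export
score_cohort <- function(cohort, snps = NULL,
                         mode = c("normalized", "literal"),
                         decile_reference = c("controls", "pooled")) {
  mode <- match.arg(mode)
  decile_reference <- match.arg(decile_reference)
  if (is.null(snps)) snps <- estimate_panel(cohort)
  w <- snp_weights(snps, mode)
  wgrs <- compute_wgrs(cohort, w)
  cgrs <- compute_cgrs(cohort)
  ref <- if (decile_reference == "controls") wgrs[cohort$status == 0] else wgrs
  out <- data.frame(subject_id = cohort$subject_id,
                    status = cohort$status,
                    smoking = cohort$smoking,
                    cgrs = cgrs,
                    cgrs_band = cgrs_band(cgrs),
                    wgrs = wgrs,
                    wgrs_decile = decile_categories(wgrs, ref),
                    stringsAsFactors = FALSE)
  class(out) <- c("grs_scores", "data.frame")
  attr(out, "weights") <- w
  attr(out, "decile_reference") <- decile_reference
  out
}

## estimate per-SNP control allele frequency and allelic OR from the cohort
estimate_panel <- function(cohort) {
  snp_ids <- attr(cohort, "snp_ids")
  rows <- lapply(snp_ids, function(s) {
    cc <- genotype_counts(cohort[[s]][cohort$status == 1])
    co <- genotype_counts(cohort[[s]][cohort$status == 0])
    orr <- allelic_or(cc, co)
    phat <- (2 * co[3] + co[2]) / (2 * sum(co))
    snp_def(s, "B", phat, orr$oratio)
  })
  do.call(snp_panel, rows)
}

#' Tabulate genotype counts from a dosage vector
#'
#' @param dosage Vector of dosages 0/1/2 (NA dropped).
#' @return Integer vector `c(n0, n1, n2)` of counts for dosage 0, 1, 2.
#' @export
genotype_counts <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  c(sum(dosage == 0), sum(dosage == 1), sum(dosage == 2))
}
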