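#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the asymptotic one-degree-of-freedom chi-square
#' goodness-of-fit test against the expected genotype counts computed from
#' the observed allele frequency; `method = "exact"` gives the
#' Levene-Haldane exact test (sum of heterozygote-count probabilities no
#' larger than the observed one, conditional on the allele counts).
#'
#' @param counts Integer vector `c(n_AA, n_AB, n_BB)` of genotype counts
#'   (B = risk allele).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A list with `statistic` (chi-square only), `p_value` and the
#'   expected counts.  A monomorphic sample returns `p_value = 1` by
#'   convention.
#' @examples
#' hwe_test(c(25, 50, 25))$p_value  # exact HWE proportions -> 1
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (length(counts) != 3L || !is_count_vec(counts))
    stop_bad_arg("counts must be three non-negative integers (n_AA, n_AB, n_BB)")
  n <- sum(counts)
  if (n == 0L) stop_bad_arg("zero genotypes")
  phat <- (2 * counts[3] + counts[2]) / (2 * n)
  expected <- n * c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
  if (phat == 0 || phat == 1)
    return(list(statistic = 0, p_value = 1, expected = expected))
  if (method == "chisq") {
    stat <- sum((counts - expected)^2 / expected)
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         expected = expected)
  } else {
    list(statistic = NA_real_, p_value = hwe_exact_p(counts),
         expected = expected)
  }
}

## Levene-Haldane exact HWE p-value: enumerate heterozygote counts with the
## observed allele counts, sum probabilities <= that of the observed table
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  nB <- 2 * counts[3] + counts[2]
  nA <- 2 * n - nB
  rare <- min(nA, nB)
  het <- seq.int(rare %% 2, rare, by = 2L)
  logp <- vapply(het, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- counts[2]
  sum(pr[pr <= pr[match(obs, het)] * (1 + 1e-12)])
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' `a/b` are exposed/unexposed in one group and `c/d` in the reference
#' group; OR = (a d)/(b c).  The 95% CI is Woolf's log-normal interval
#' `exp(log OR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))` and the two-sided p-value
#' comes from the log-OR z statistic.  Any zero cell triggers the
#' Haldane-Anscombe 0.5 continuity correction, flagged in the result.
#'
#' @param a,b,c,d Non-negative counts.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `oratio`, `ci95`, `p_value`, `corrected`.
#' @export
or_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (!is_count_vec(cells)) stop_bad_arg("2x2 cells must be non-negative counts")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  lor <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(oratio = exp(lor),
       ci95 = exp(lor + c(-1, 1) * z * se),
       p_value = 2 * stats::pnorm(abs(lor / se), lower.tail = FALSE),
       corrected = corrected)
}

#' Allelic odds ratio from case and control genotype counts
#'
#' Genotypes are collapsed to allele counts (risk alleles = `2 n_BB +
#' n_AB`), and the 2x2 allele table is passed through [or_2x2()], i.e. the
#' crude per-allele odds ratio with a Woolf interval.
#'
#' @param case_counts,control_counts Genotype counts `c(n_AA, n_AB, n_BB)`.
#' @return List with `oratio`, `ci95`, `p_value`, `corrected`, plus the
#'   allele counts used.
#' @export
allelic_or <- function(case_counts, control_counts) {
  for (x in list(case_counts, control_counts))
    if (length(x) != 3L || !is_count_vec(x))
      stop_bad_arg("genotype counts must be three non-negative integers")
  a <- 2 * case_counts[3] + case_counts[2]      # risk alleles, cases
  b <- 2 * case_counts[1] + case_counts[2]      # non-risk alleles, cases
  c <- 2 * control_counts[3] + control_counts[2]
  d <- 2 * control_counts[1] + control_counts[2]
  if (a + b == 0 || c + d == 0) stop_bad_arg("empty allele total")
  res <- or_2x2(a, b, c, d)
  res$allele_counts <- c(case_risk = a, case_nonrisk = b,
                         control_risk = c, control_nonrisk = d)
  res
}

#' Liability-scale variance explained by one SNP
#'
#' Under a liability threshold model with additive allelic effect
#' `beta = ln(OR)` on a unit-variance liability, a biallelic locus with
#' risk-allele frequency `p` contributes `2p(1-p) beta^2` of the liability
#' variance.  Returned as a fraction; multiply by 100 for percent.
#'
#' @inheritParams average_relative_risk
#' @return Fraction of liability variance (>= 0); 0 at `p` of 0 or 1 by
#'   continuity.
#' @examples
#' 100 * variance_explained(0.41, 1.18)  # 1.33 (as %)
#' @export
variance_explained <- function(p, oratio) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_bad_arg("p must lie in [0, 1]")
  if (!is.numeric(oratio) || any(is.na(oratio)) || any(oratio <= 0))
    stop_bad_arg("oratio must be > 0")
  2 * p * (1 - p) * log(oratio)^2
}

#' Pairwise linkage disequilibrium D' from unphased dosages
#'
#' Haplotype frequencies for the two loci are estimated from the 3x3
#' genotype table by expectation-maximisation (the double-heterozygote cell
#' is the only ambiguous one), then `D = p_AB - p_A p_B` is scaled by its
#' maximum attainable magnitude given the allele frequencies.
#'
#' @param dosages_a,dosages_b Paired dosage vectors (0/1/2, NA allowed;
#'   pairs with any NA are dropped).
#' @param tol EM convergence tolerance on the haplotype frequency.
#' @return List with `dprime`, `d`, `haplotype_freqs` (pAB, pAb, paB, pab
#'   with "A"/"B" the risk alleles at each locus) and `n_pairs`.
#' @export
ld_dprime <- function(dosages_a, dosages_b, tol = 1e-12) {
  if (length(dosages_a) != length(dosages_b))
    stop_bad_arg("dosage vectors must be paired (equal length)")
  keep <- !is.na(dosages_a) & !is.na(dosages_b)
  da <- dosages_a[keep]; db <- dosages_b[keep]
  if (length(da) < 2L) stop_bad_arg("fewer than 2 complete pairs")
  pA <- mean(da) / 2; pB <- mean(db) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop_bad_arg("monomorphic locus: D' undefined")
  n <- length(da)
  # 3x3 genotype table
  tab <- table(factor(da, 0:2), factor(db, 0:2))
  # EM over the phase of double heterozygotes
  pAB <- pA * pB
  repeat {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    ndh <- tab[2, 2]
    # expected count of AB/ab phase among double heterozygotes
    denom <- pAB * pab + pAb * paB
    eAB <- if (denom > 0) ndh * pAB * pab / denom else ndh / 2
    nAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + eAB
    new <- nAB / (2 * n)
    if (abs(new - pAB) < tol) { pAB <- new; break }
    pAB <- new
  }
  d <- pAB - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  list(dprime = if (dmax > 0) abs(d) / dmax else 0, d = d,
       haplotype_freqs = c(pAB = pAB, pAb = pA - pAB,
                           paB = pB - pAB, pab = 1 - pA - pB + pAB),
       n_pairs = n)
}

#' Per-SNP association table for a cohort
#'
#' For every SNP column: Hardy-Weinberg p-value in controls, control
#' risk-allele frequency, crude allelic odds ratio with Woolf 95% CI and
#' p-value, and liability-scale variance explained (computed from the
#' control frequency and the estimated OR, as a percentage).  A per-SNP
#' log-additive logistic fit is available as a cross-check via
#' `logistic_check = TRUE` (adds the trend OR and p).
#'
#' @param cohort A `grs_cohort`.
#' @param logistic_check Also fit `status ~ dosage` per SNP.
#' @return Data frame, one row per SNP.
#' @export
assoc_table <- function(cohort, logistic_check = FALSE) {
  validate_cohort(cohort)
  snp_ids <- attr(cohort, "snp_ids")
  rows <- lapply(snp_ids, function(s) {
    cc <- genotype_counts(cohort[[s]][cohort$status == 1])
    co <- genotype_counts(cohort[[s]][cohort$status == 0])
    hwe <- hwe_test(co)
    orr <- allelic_or(cc, co)
    freq <- (2 * co[3] + co[2]) / (2 * sum(co))
    row <- data.frame(snp_id = s,
                      hwe_p = hwe$p_value,
                      allele_freq = freq,
                      oratio = orr$oratio,
                      ci_low = orr$ci95[1], ci_high = orr$ci95[2],
                      p_assoc = orr$p_value,
                      var_explained_pct = 100 * variance_explained(freq, orr$oratio),
                      stringsAsFactors = FALSE)
    if (logistic_check) {
      d <- cohort[[s]]
      fit <- stats::glm(cohort$status ~ d, family = stats::binomial())
      row$trend_or <- exp(stats::coef(fit)[["d"]])
      row$trend_p <- summary(fit)$coefficients["d", 4]
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an association table as TSV
#' @param assoc Result of [assoc_table()].
#' @param path Output path.
#' @export
write_assoc_table <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
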