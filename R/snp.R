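#' Define a risk locus
#'
#' A SNP is described by the minimum needed for risk-score work: an
#' identifier, the risk (high-risk) allele label, the risk-allele frequency
#' `p` and the per-allele odds ratio.  Under the log-additive model the three
#' genotypes carrying 0, 1 and 2 risk alleles have relative risks 1, OR and
#' OR^2.
#'
#' @param snp_id Character identifier (e.g. an rs number).
#' @param risk_allele Single-character allele label (`"A"`, `"C"`, `"G"`,
#'   `"T"`).
#' @param p Risk-allele frequency, in \[0, 1\].
#' @param oratio Per-allele odds ratio, strictly positive.
#' @return A one-row `data.frame` with columns `snp_id`, `risk_allele`, `p`,
#'   `oratio`.
#' @examples
#' snp_def("rs2736100", "C", 0.41, 1.18)
#' @export
snp_def <- function(snp_id, risk_allele, p, oratio) {
  stopifnot(is.character(snp_id), length(snp_id) == 1L, nzchar(snp_id))
  stopifnot(is.character(risk_allele), length(risk_allele) == 1L)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_bad_arg("risk-allele frequency must lie in [0, 1], got %s", format(p))
  if (!is.numeric(oratio) || length(oratio) != 1L || is.na(oratio) || oratio <= 0)
    stop_bad_arg("odds ratio must be > 0, got %s", format(oratio))
  data.frame(snp_id = snp_id, risk_allele = risk_allele,
             p = as.numeric(p), oratio = as.numeric(oratio),
             stringsAsFactors = FALSE)
}

#' Assemble a SNP panel
#'
#' @param ... One-row data frames from [snp_def()].
#' @return A `data.frame`, one row per SNP.
#' @export
snp_panel <- function(...) {
  panel <- do.call(rbind, list(...))
  if (anyDuplicated(panel$snp_id))
    stop_bad_arg("duplicate snp_id in panel")
  panel
}

#' The default four-SNP lung-cancer panel
#'
#' Four independently replicated lung-cancer susceptibility loci (TERT,
#' CLPTM1L, RGS17, TP63 regions) with their risk-allele frequencies and
#' per-allele odds ratios as observed in a large Han Chinese case-control
#' study.  These are the parameters the default cohort simulator uses.
#'
#' @return A 4-row SNP panel `data.frame`.
#' @examples
#' default_snp_panel()
#' @export
default_snp_panel <- function() {
  snp_panel(
    snp_def("rs2736100", "C", 0.41, 1.18),
    snp_def("rs402710",  "C", 0.68, 1.10),
    snp_def("rs4083914", "G", 0.14, 1.15),
    snp_def("rs4488809", "T", 0.47, 1.21)
  )
}

#' Simulation configuration for a case-control cohort
#'
#' Bundles everything the cohort simulator needs: the SNP panel, the
#' three-level smoking distribution in the source (control-like) population,
#' the per-level smoking odds ratio, the population disease prevalence used
#' to anchor the logistic intercept, the target case/control counts, an
#' optional missing-genotype rate, and the seed.
#'
#' Defaults reproduce the study design the package's tests emulate: 2,283
#' cases and 2,785 controls; smoking categories never/light/heavy with the
#' observed control distribution (54.5/19.5/26.1%); per-level smoking OR
#' 1.67; population prevalence 1% (rare-disease regime, so odds ratios and
#' relative risks are interchangeable); genotype missingness 0.5%.
#'
#' @param snps SNP panel (see [snp_panel()]).
#' @param smoking_dist Length-3 probability vector over never/light/heavy
#'   smoking in the source population; must sum to 1.
#' @param smoking_or Per-level smoking odds ratio (> 0).
#' @param prevalence Marginal disease probability in the source population.
#' @param n_cases,n_controls Target counts (> 0).
#' @param missing_rate Per-genotype missing-completely-at-random rate.
#' @param seed Integer seed governing every random draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(snps = default_snp_panel(),
                       smoking_dist = c(1517, 542, 726) / 2785,
                       smoking_or = 1.67,
                       prevalence = 0.01,
                       n_cases = 2283,
                       n_controls = 2785,
                       missing_rate = 0.005,
                       seed = 1) {
  stopifnot(is.data.frame(snps), nrow(snps) >= 1L,
            all(c("snp_id", "p", "oratio") %in% names(snps)))
  if (length(smoking_dist) != 3L || any(smoking_dist < 0) ||
      abs(sum(smoking_dist) - 1) > 1e-8)
    stop_bad_arg("smoking_dist must be a 3-vector of probabilities summing to 1")
  if (smoking_or <= 0) stop_bad_arg("smoking_or must be > 0")
  if (prevalence <= 0 || prevalence >= 1)
    stop_bad_arg("prevalence must lie in (0, 1)")
  if (n_cases < 1 || n_controls < 1)
    stop_bad_arg("n_cases and n_controls must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_bad_arg("missing_rate must lie in [0, 1)")
  structure(list(snps = snps,
                 smoking_dist = as.numeric(smoking_dist),
                 smoking_or = as.numeric(smoking_or),
                 prevalence = as.numeric(prevalence),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 missing_rate = as.numeric(missing_rate),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a JSON file
#'
#' Key names match the [sim_config()] arguments; `snps` is an array of
#' objects with `snp_id`, `risk_allele`, `p`, `oratio`.
#'
#' @param path Path to a JSON file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  snps <- if (is.null(raw$snps)) default_snp_panel() else {
    do.call(snp_panel, lapply(seq_len(nrow(raw$snps)), function(i)
      snp_def(raw$snps$snp_id[i], raw$snps$risk_allele[i] %||% "A",
              raw$snps$p[i], raw$snps$oratio[i])))
  }
  cfg <- sim_config(snps = snps)
  for (key in c("smoking_dist", "smoking_or", "prevalence", "n_cases",
                "n_controls", "missing_rate", "seed"))
    if (!is.null(raw[[key]])) cfg[[key]] <- raw[[key]]
  do.call(sim_config, unclass(cfg))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d SNPs, %d cases / %d controls, prevalence %.3g, seed %d\n",
              nrow(x$snps), x$n_cases, x$n_controls, x$prevalence, x$seed))
  invisible(x)
}
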