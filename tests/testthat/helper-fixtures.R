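# shared fixtures built in code

# the four-SNP study panel (frequencies / per-allele ORs as printed)
panel4 <- function() default_snp_panel()

# printed three-level smoking contingency rows (cases, controls)
smoking_counts <- function() {
  data.frame(label = c("never", "light", "heavy"),
             cases = c(801L, 416L, 1066L),
             controls = c(1517L, 542L, 726L))
}

# printed cGRS band rows
cgrs_counts <- function() {
  data.frame(label = c("0-1", "2", "3", "4", "5", ">=6"),
             cases = c(125L, 337L, 589L, 600L, 435L, 197L),
             controls = c(226L, 465L, 733L, 740L, 453L, 168L))
}

# a small hand-written cohort with a missing genotype
tiny_cohort <- function() {
  as_cohort(data.frame(
    subject_id = c("a", "b", "c", "d"),
    status = c(1L, 1L, 0L, 0L),
    smoking = c(2L, 0L, 1L, 0L),
    snpA = c(2L, 1L, 0L, 1L),
    snpB = c(1L, NA, 0L, 2L),
    stringsAsFactors = FALSE))
}

# fast small simulation config
small_config <- function(seed = 1, n = 300, prevalence = 0.05, ...) {
  sim_config(n_cases = n, n_controls = n, prevalence = prevalence,
             missing_rate = 0, seed = seed, ...)
}
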