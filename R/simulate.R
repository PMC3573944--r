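#' Simulate a case-control cohort under a log-additive odds model
#'
#' Population individuals are drawn with independent Hardy-Weinberg
#' genotypes (`dosage ~ Binomial(2, p)` per SNP), smoking from the
#' configured three-level distribution, and disease status from
#' `logistic(alpha + sum(log(OR_snp) * dosage) + log(OR_smoke) * smoking)`.
#' The intercept `alpha` is solved (by exact enumeration over all
#' genotype-by-smoking cells) so the marginal disease probability equals the
#' configured prevalence.  Individuals are sampled until the target case and
#' control counts are reached; the first `n_cases` cases and `n_controls`
#' controls (in draw order) form the cohort, i.e. case-control ascertainment
#' by rejection sampling.  Everything is deterministic given `config$seed`.
#'
#' Smoking is generated independently of genotype (no gene-environment
#' correlation), matching the additive model the downstream analysis fits.
#' Missing genotypes, if `missing_rate > 0`, are injected completely at
#' random after ascertainment.
#'
#' @param config A [sim_config()] object.
#' @param max_draws Draw budget: maximum number of population individuals to
#'   sample before giving up (default 5,000 times the target cohort size).
#' @return A `grs_cohort` with `n_cases + n_controls` rows, cases first.
#' @examples
#' cfg <- sim_config(n_cases = 100, n_controls = 100, prevalence = 0.1, seed = 7)
#' sim <- simulate_cohort(cfg)
#' table(sim$status)
#' @export
simulate_cohort <- function(config,
                            max_draws = 5000 * (config$n_cases + config$n_controls)) {
  stopifnot(inherits(config, "sim_config"))
  beta <- log(config$snps$oratio)
  p <- config$snps$p
  alpha <- solve_intercept(p, beta, config$smoking_dist,
                           log(config$smoking_or), config$prevalence)
  K <- length(p)
  n_cases <- config$n_cases
  n_controls <- config$n_controls

  with_seed(config$seed, {
    cases <- vector("list", 0L)
    controls <- vector("list", 0L)
    got_ca <- 0L; got_co <- 0L; drawn <- 0L
    batch <- max(20000L, as.integer(ceiling(1.2 * n_cases / config$prevalence / 4)))
    while (got_ca < n_cases || got_co < n_controls) {
      if (drawn >= max_draws)
        stop_bad_arg(paste0(
          "draw budget exhausted after %d individuals: still need %d case(s) ",
          "and %d control(s); raise max_draws or prevalence"),
          drawn, max(0L, n_cases - got_ca), max(0L, n_controls - got_co))
      n <- min(batch, max_draws - drawn)
      drawn <- drawn + n
      D <- vapply(p, function(pk) stats::rbinom(n, 2L, pk), integer(n))
      if (n == 1L) D <- matrix(D, nrow = 1L)
      smoking <- sample.int(3L, n, replace = TRUE,
                            prob = config$smoking_dist) - 1L
      eta <- alpha + as.vector(D %*% beta) + log(config$smoking_or) * smoking
      y <- stats::rbinom(n, 1L, stats::plogis(eta))
      if (got_ca < n_cases) {
        idx <- which(y == 1L)
        idx <- idx[seq_len(min(length(idx), n_cases - got_ca))]
        if (length(idx)) {
          cases[[length(cases) + 1L]] <-
            cbind(D[idx, , drop = FALSE], smoking[idx])
          got_ca <- got_ca + length(idx)
        }
      }
      if (got_co < n_controls) {
        idx <- which(y == 0L)
        idx <- idx[seq_len(min(length(idx), n_controls - got_co))]
        if (length(idx)) {
          controls[[length(controls) + 1L]] <-
            cbind(D[idx, , drop = FALSE], smoking[idx])
          got_co <- got_co + length(idx)
        }
      }
    }
    ca <- do.call(rbind, cases)
    co <- do.call(rbind, controls)
    m <- rbind(ca, co)
    dos <- m[, seq_len(K), drop = FALSE]
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(length(dos)) < config$missing_rate,
                     nrow = nrow(dos))
      dos[miss] <- NA_integer_
    }
    df <- data.frame(subject_id = sprintf("S%05d", seq_len(nrow(m))),
                     status = rep(c(1L, 0L), c(n_cases, n_controls)),
                     smoking = as.integer(m[, K + 1L]),
                     stringsAsFactors = FALSE)
    for (k in seq_len(K)) df[[config$snps$snp_id[k]]] <- as.integer(dos[, k])
    as_cohort(df, config$snps$snp_id)
  })
}

## solve logistic intercept so that the marginal disease probability over the
## exact genotype-by-smoking distribution equals `prevalence`
solve_intercept <- function(p, beta, smoking_dist, beta_smoke, prevalence) {
  K <- length(p)
  if (3^K > 600000)
    stop_bad_arg("too many SNPs (%d) for exact intercept enumeration", K)
  cells <- as.matrix(expand.grid(rep(list(0:2), K)))
  w <- rep(1, nrow(cells))
  for (k in seq_len(K)) {
    hw <- c((1 - p[k])^2, 2 * p[k] * (1 - p[k]), p[k]^2)
    w <- w * hw[cells[, k] + 1L]
  }
  eta_g <- as.vector(cells %*% beta)
  # fold in smoking: outer over 3 levels
  w_all <- as.vector(outer(w, smoking_dist))
  eta_all <- as.vector(outer(eta_g, beta_smoke * (0:2), `+`))
  f <- function(a) sum(w_all * stats::plogis(a + eta_all)) - prevalence
  stats::uniroot(f, interval = c(-40, 40), tol = 1e-12)$root
}
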