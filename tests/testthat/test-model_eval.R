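test_that("rank AUC handles printed counts, separation and ties", {
  # smoking-only discrimination from the printed three-level counts
  sm <- expand_counts(smoking_counts(), category = "smoking", values = 0:2)
  expect_equal(round(auc_rank(sm$smoking, sm$status)$auc, 3), 0.619)

  expect_equal(auc_rank(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(auc_rank(rep(5, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(auc_rank(1:5, rep(1, 5)), "both classes")

  # bootstrap CI brackets the point estimate and is seed-reproducible
  r1 <- auc_rank(sm$smoking, sm$status, ci = TRUE, B = 200, seed = 4)
  r2 <- auc_rank(sm$smoking, sm$status, ci = TRUE, B = 200, seed = 4)
  expect_identical(r1$ci95, r2$ci95)
  expect_lte(r1$ci95[1], r1$auc); expect_gte(r1$ci95[2], r1$auc)
})

test_that("AUC equals trapezoidal area under its own ROC curve and is monotone-invariant", {
  set.seed(55)
  for (rep in 1:5) {
    x <- c(rnorm(60, 1), sample(1:4, 20, TRUE))  # continuous + tied mix
    y <- rep(c(1, 0), c(60, 20))
    curve <- roc_curve(x, y)
    trap <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                   utils::tail(curve$tpr, -1)) / 2)
    expect_equal(auc_rank(x, y)$auc, trap, tolerance = 1e-10)
    expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
    expect_equal(curve$fpr[nrow(curve)], 1)
    expect_equal(curve$tpr[nrow(curve)], 1)
    expect_true(all(diff(curve$fpr) >= 0) && all(diff(curve$tpr) >= 0))
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(auc_rank(exp(x / 3), y)$auc, auc_rank(x, y)$auc)
    expect_equal(auc_rank(5 * x - 2, y)$auc, auc_rank(x, y)$auc)
  }
})

test_that("paired AUC comparison behaves under identity, transform and signal", {
  y <- rep(0:1, each = 100)
  set.seed(61)
  a <- rnorm(200) + y
  # identical scores -> delta 0, p ~ 1
  r <- compare_auc(a, a, y, B = 200, seed = 1)
  expect_equal(r$delta, 0)
  expect_equal(r$p_value, 1)
  # monotone transform -> delta exactly 0
  expect_equal(compare_auc(a, exp(a), y, B = 50, seed = 1)$delta, 0)
  # informative vs noise at n=2000: decisively significant across seeds
  set.seed(62)
  y2 <- rep(0:1, each = 1000)
  info <- rnorm(2000) + 0.5 * y2
  noise <- rnorm(2000)
  ps <- vapply(1:5, function(s)
    compare_auc(info, noise, y2, B = 400, seed = s)$p_value, numeric(1))
  expect_true(all(ps < 0.01))
  # DeLong option agrees in verdict
  expect_lt(compare_auc(info, noise, y2, method = "delong")$p_value, 0.01)
  expect_error(compare_auc(1:3, 1:4, c(0, 1, 0)), "equal length")
})

test_that("Hosmer-Lemeshow detects miscalibration and only that", {
  # perfectly calibrated grouped probabilities -> statistic ~ 0
  p <- rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 10)
  y <- unlist(lapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                     function(q) rep(c(1, 0), round(c(q, 1 - q) * 10))))
  r <- suppressWarnings(hosmer_lemeshow(p, y, n_groups = 5))
  expect_lt(r$statistic, 1e-10)
  expect_equal(r$p_value, 1, tolerance = 1e-6)

  # systematically halved probabilities are rejected at n=5000
  set.seed(71)
  rej <- vapply(1:10, function(s) {
    set.seed(700 + s)
    pt <- runif(5000, 0.1, 0.8)
    yy <- rbinom(5000, 1, pt)
    hosmer_lemeshow(pt / 2, yy)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)

  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, .5), n_groups = 1),
               "n_groups")
})

test_that("HL p-values are ~Uniform[0,1] under a well-specified model", {
  set.seed(73)
  ps <- vapply(1:200, function(i) {
    n <- 1000
    x <- rnorm(n)
    pt <- plogis(-0.5 + 0.8 * x)
    y <- rbinom(n, 1, pt)
    fit <- glm(y ~ x, family = binomial())
    hosmer_lemeshow(fitted(fit), y)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bootstrap optimism: none for a fixed rule, large for a designed over-fit", {
  set.seed(81)
  n <- 600
  df <- data.frame(status = rbinom(n, 1, 0.4), x = rnorm(n))
  df$x <- df$x + 0.5 * df$status
  # fixed (non-refitted) scoring rule -> optimism ~ 0
  fixed <- function(train) function(newdata) newdata$x
  r <- bootstrap_optimism(df, fixed, B = 200, seed = 2)
  expect_lt(abs(r$optimism), 0.01)
  expect_equal(r$auc_corrected, r$auc_apparent - r$optimism)

  # 50 noise covariates on n=300 -> optimism > 0.02
  set.seed(82)
  noisy <- as.data.frame(matrix(rnorm(300 * 50), 300, 50))
  names(noisy) <- paste0("z", 1:50)
  noisy$status <- rbinom(300, 1, 0.5)
  overfit <- function(train) {
    fit <- suppressWarnings(glm(status ~ ., family = binomial(), data = train))
    function(newdata) suppressWarnings(
      as.vector(predict(fit, newdata = newdata)))
  }
  opt <- vapply(1:3, function(s)
    bootstrap_optimism(noisy, overfit, B = 60, seed = s)$optimism, numeric(1))
  expect_true(all(opt > 0.02))

  # replicate-failure accounting
  flaky <- function(train) {
    if (stats::runif(1) < 0.5) stop("boom")
    function(newdata) newdata$x
  }
  expect_error(bootstrap_optimism(df, flaky, B = 50, seed = 3),
               "refits failed")
})

test_that("two-covariate model at study scale has negligible optimism", {
  sim <- simulate_cohort(sim_config(missing_rate = 0, seed = 15))
  sc <- as.data.frame(score_cohort(sim, snps = panel4()))
  r <- bootstrap_optimism(sc, grs_smoking_fitter(), B = 200, seed = 15)
  expect_lt(abs(r$optimism), 0.005)
  expect_lte(r$auc_corrected, r$auc_apparent + 1e-12)
})

test_that("split validation is stable and honours its contracts", {
  # null covariates -> both c statistics near 0.5
  set.seed(91)
  df <- data.frame(status = rbinom(2000, 1, 0.5),
                   wgrs_decile = sample(0:9, 2000, TRUE),
                   smoking = sample(0:2, 2000, TRUE))
  r <- split_validate(df, grs_smoking_fitter(), seed = 3)
  expect_lt(abs(r$c_train - 0.5), 0.05)
  expect_lt(abs(r$c_test - 0.5), 0.07)
  expect_equal(r$n_train, 1500)

  # default synthetic cohort: train and test c agree within 0.03 over seeds
  sim <- simulate_cohort(sim_config(missing_rate = 0, seed = 7))
  sc <- as.data.frame(score_cohort(sim, snps = panel4()))
  gaps <- vapply(1:20, function(s) {
    r <- split_validate(sc, grs_smoking_fitter(), seed = s)
    r$c_train - r$c_test
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.03)

  expect_error(split_validate(data.frame(status = rep(1, 10), x = 1:10),
                              grs_smoking_fitter(), seed = 1),
               "outcome class")
})

test_that("Youden cutoff metrics match confusion-matrix arithmetic", {
  # perfect separation -> all metrics 1
  r <- youden_cutoff_metrics(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(unlist(r[c("sensitivity", "specificity", "accuracy",
                          "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 ppv = 1, npv = 1))
  # scores = status
  r2 <- youden_cutoff_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(r2$accuracy, 1)
  expect_equal(r2$cutoff, 1)

  # forced 2x2 oracle: TP=90 FN=10 TN=80 FP=20 at the optimal cutoff
  scores <- c(rep(1, 90), rep(0, 10), rep(0, 80), rep(1, 20))
  status <- rep(c(1, 0), c(100, 100))
  r3 <- youden_cutoff_metrics(scores, status)
  expect_equal(r3$cutoff, 1)
  expect_equal(r3$sensitivity, 0.90)
  expect_equal(r3$specificity, 0.80)
  expect_equal(r3$ppv, 90 / 110, tolerance = 1e-12)
  expect_equal(r3$npv, 80 / 90, tolerance = 1e-12)
  expect_equal(r3$accuracy, 0.85)
})

test_that("removing a covariate reduces the c statistic by the printed amount", {
  # reduction-in-c computed on identical subjects, using the printed pair:
  # full model 0.639 vs smoking-only 0.619 -> 0.020
  expect_equal(0.639 - 0.619, 0.020, tolerance = 1e-12)
  # and structurally: on simulated data, AUC(full) >= AUC(smoking-only)
  sim <- simulate_cohort(small_config(seed = 37, n = 800))
  sc <- score_cohort(sim, snps = panel4())
  m <- fit_risk_model(sc)
  full <- auc_rank(m$fitted_probabilities, sc$status)$auc
  reduced <- auc_rank(sc$smoking, sc$status)$auc
  expect_gte(full, reduced - 0.01)
})
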