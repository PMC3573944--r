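#' Rank-based AUC (concordance statistic)
#'
#' The area under the ROC curve computed as the Mann-Whitney probability
#' that a random case outscores a random control, counting ties as one
#' half.  The optional confidence interval is a seeded bootstrap percentile
#' interval over subjects.
#'
#' @param scores Numeric score per subject (higher = more case-like).
#' @param status Binary vector (1 = case), same length.
#' @param ci Compute a bootstrap percentile CI?
#' @param B Bootstrap resamples for the CI (default 1000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return List of class `roc_result`: `auc`, `ci95` (or NULL), `n_cases`,
#'   `n_controls`.
#' @export
auc_rank <- function(scores, status, ci = FALSE, B = 1000, seed = 1,
                     conf_level = 0.95) {
  stopifnot(length(scores) == length(status))
  keep <- !is.na(scores) & !is.na(status)
  scores <- scores[keep]; status <- status[keep]
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0L || n0 == 0L) stop_bad_arg("both classes must be present")
  auc <- auc_stat(scores, status, n1, n0)
  ci95 <- NULL
  if (ci) {
    ci95 <- with_seed(seed, {
      idx1 <- which(status == 1); idx0 <- which(status == 0)
      reps <- vapply(seq_len(B), function(i) {
        s <- c(sample(idx1, n1, replace = TRUE),
               sample(idx0, n0, replace = TRUE))
        auc_stat(scores[s], status[s], n1, n0)
      }, numeric(1))
      unname(stats::quantile(reps, c((1 - conf_level) / 2,
                                     1 - (1 - conf_level) / 2)))
    })
  }
  structure(list(auc = auc, ci95 = ci95, n_cases = n1, n_controls = n0),
            class = "roc_result")
}

auc_stat <- function(scores, status, n1 = sum(status == 1),
                     n0 = sum(status == 0)) {
  r <- rank(scores)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f", x$auc))
  if (!is.null(x$ci95)) cat(sprintf(" (%.3f-%.3f)", x$ci95[1], x$ci95[2]))
  cat(sprintf("  [%d cases / %d controls]\n", x$n_cases, x$n_controls))
  invisible(x)
}

#' ROC curve points
#'
#' Ordered (1-specificity, sensitivity) points, one step per distinct score
#' value, starting at (0,0) and ending at (1,1).  Trapezoidal integration
#' of this curve equals [auc_rank()] exactly.
#'
#' @inheritParams auc_rank
#' @return Data frame with columns `threshold`, `fpr`, `tpr`; the leading
#'   (0,0) row carries threshold `Inf`.
#' @export
roc_curve <- function(scores, status) {
  stopifnot(length(scores) == length(status))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- status[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop_bad_arg("both classes must be present")
  # collapse tied scores into single steps
  last <- !duplicated(s, fromLast = TRUE) # last index of each tied block
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}

#' Compare two paired AUCs
#'
#' Two-sided test of equal discrimination for two scores measured on the
#' same subjects.  Default is a paired bootstrap over subjects (resample,
#' recompute both AUCs, examine the resampled distribution of the
#' difference); `method = "delong"` gives the asymptotic DeLong test.
#'
#' @param scores_a,scores_b Paired numeric scores.
#' @param status Binary status vector.
#' @param method `"bootstrap"` (default) or `"delong"`.
#' @param B Bootstrap resamples.
#' @param seed Seed.
#' @return List: `auc_a`, `auc_b`, `delta` (a minus b), `p_value`, `method`.
#' @export
compare_auc <- function(scores_a, scores_b, status,
                        method = c("bootstrap", "delong"),
                        B = 2000, seed = 1) {
  method <- match.arg(method)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(status))
    stop_bad_arg("scores_a, scores_b and status must have equal length")
  auc_a <- auc_stat(scores_a, status)
  auc_b <- auc_stat(scores_b, status)
  delta <- auc_a - auc_b
  if (method == "bootstrap") {
    idx1 <- which(status == 1); idx0 <- which(status == 0)
    reps <- with_seed(seed, vapply(seq_len(B), function(i) {
      s <- c(sample(idx1, replace = TRUE), sample(idx0, replace = TRUE))
      auc_stat(scores_a[s], status[s]) - auc_stat(scores_b[s], status[s])
    }, numeric(1)))
    if (all(reps == 0) && delta == 0) {
      p <- 1
    } else {
      p <- min(1, 2 * min(mean(reps <= 0), mean(reps >= 0)))
    }
  } else {
    p <- delong_p(scores_a, scores_b, status, delta)
  }
  list(auc_a = auc_a, auc_b = auc_b, delta = delta, p_value = p,
       method = method)
}

## DeLong placement-value covariance test for paired AUC difference
delong_p <- function(sa, sb, status, delta) {
  cases <- status == 1
  v <- function(s) {
    x <- s[cases]; y <- s[!cases]
    m <- length(x); n <- length(y)
    v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                  numeric(1))
    v01 <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m,
                  numeric(1))
    list(v10 = v10, v01 = v01)
  }
  pa <- v(sa); pb <- v(sb)
  m <- sum(cases); n <- sum(!cases)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_delta <= 0) return(1)
  2 * stats::pnorm(abs(delta) / sqrt(var_delta), lower.tail = FALSE)
}

#' Hosmer-Lemeshow calibration test
#'
#' Subjects are binned into `n_groups` groups by fitted-probability
#' quantiles; the statistic is `sum((O - E)^2 / (E (1 - E/n_g)))` over
#' groups with `O` observed and `E` expected events, referred to a
#' chi-square with `n_groups - 2` degrees of freedom.  Bins that would be
#' empty (heavily tied probabilities) are merged, with a warning.
#'
#' @param fitted_probabilities Per-subject fitted event probabilities.
#' @param status Binary outcomes.
#' @param n_groups Number of groups (default 10).
#' @return List: `statistic`, `p_value`, `df`, `table` (per-group observed /
#'   expected / size).
#' @export
hosmer_lemeshow <- function(fitted_probabilities, status, n_groups = 10) {
  stopifnot(length(fitted_probabilities) == length(status))
  if (n_groups < 2) stop_bad_arg("n_groups must be >= 2")
  br <- unique(stats::quantile(fitted_probabilities,
                               probs = seq(0, 1, length.out = n_groups + 1),
                               names = FALSE))
  if (length(br) < n_groups + 1)
    warning("tied fitted probabilities: bins merged (",
            length(br) - 1, " groups used)")
  if (length(br) < 3) stop_bad_arg("fewer than 2 distinct probability bins")
  g <- cut(fitted_probabilities, breaks = br, include.lowest = TRUE)
  O <- tapply(status, g, sum)
  E <- tapply(fitted_probabilities, g, sum)
  n_g <- tapply(status, g, length)
  keep <- !is.na(n_g) & n_g > 0
  O <- O[keep]; E <- E[keep]; n_g <- n_g[keep]
  denom <- E * (1 - E / n_g)
  denom[denom < 1e-12] <- 1e-12
  stat <- sum((O - E)^2 / denom)
  df <- length(O) - 2
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df,
       table = data.frame(n = as.vector(n_g), observed = as.vector(O),
                          expected = as.vector(E)))
}

#' Bootstrap optimism correction (Harrell's procedure)
#'
#' For each of `B` bootstrap resamples of the data the model is refitted on
#' the resample and its AUC computed both on the resample and on the
#' original data; the optimism is the mean of (bootstrap AUC minus original
#' AUC), and the corrected AUC is the apparent AUC minus the optimism.
#'
#' @param data Data frame with a binary `status` column.
#' @param fit_fun Function `data -> predictor`, where the predictor is a
#'   function `data -> numeric scores`.  Refitted inside every replicate.
#' @param B Number of replicates (default 1000).
#' @param seed Seed.
#' @param max_fail_frac Replicates whose refit errors are dropped; failing
#'   more than this fraction aborts.
#' @return List: `auc_apparent`, `optimism`, `auc_corrected`, `B_used`,
#'   `B_failed`.
#' @export
bootstrap_optimism <- function(data, fit_fun, B = 1000, seed = 1,
                               max_fail_frac = 0.1) {
  stopifnot(B >= 1, "status" %in% names(data))
  predictor <- fit_fun(data)
  apparent <- auc_stat(predictor(data), data$status)
  n <- nrow(data)
  opts <- with_seed(seed, vapply(seq_len(B), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, , drop = FALSE]
    tryCatch({
      pred_b <- fit_fun(boot)
      auc_stat(pred_b(boot), boot$status) -
        auc_stat(pred_b(data), data$status)
    }, error = function(e) NA_real_)
  }, numeric(1)))
  failed <- sum(is.na(opts))
  if (failed > max_fail_frac * B)
    stop_bad_arg("%d of %d bootstrap refits failed", failed, B)
  optimism <- mean(opts, na.rm = TRUE)
  list(auc_apparent = apparent, optimism = optimism,
       auc_corrected = apparent - optimism,
       B_used = B - failed, B_failed = failed)
}

#' Split-sample internal validation
#'
#' Randomly splits the data into a training fraction (default 75%) and a
#' test fraction, refits the model on the training set and reports the
#' c statistic on both sets.
#'
#' @inheritParams bootstrap_optimism
#' @param train_fraction Fraction of subjects in the training set.
#' @return List: `c_train`, `c_test`, `n_train`, `n_test`.
#' @export
split_validate <- function(data, fit_fun, train_fraction = 0.75, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            "status" %in% names(data))
  n <- nrow(data)
  split_once <- function() {
    idx <- sample.int(n, floor(train_fraction * n))
    list(train = data[idx, , drop = FALSE],
         test = data[-idx, , drop = FALSE])
  }
  with_seed(seed, {
    sp <- split_once()
    ok <- function(d) length(unique(d$status)) == 2L
    if (!ok(sp$train) || !ok(sp$test)) sp <- split_once()
    if (!ok(sp$train) || !ok(sp$test))
      stop_bad_arg("a split lacks one outcome class even after a resplit")
    predictor <- fit_fun(sp$train)
    list(c_train = auc_stat(predictor(sp$train), sp$train$status),
         c_test = auc_stat(predictor(sp$test), sp$test$status),
         n_train = nrow(sp$train), n_test = nrow(sp$test))
  })
}

#' Youden-optimal cutoff and confusion metrics
#'
#' Scans the distinct score values as candidate cutoffs (classification
#' rule: score >= cutoff is called positive), picks the cutoff maximising
#' sensitivity + specificity (Youden's J), breaking ties toward higher
#' specificity, and reports the confusion metrics at that cutoff.
#'
#' @inheritParams auc_rank
#' @return List: `cutoff`, `sensitivity`, `specificity`, `accuracy`, `ppv`,
#'   `npv`, and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
youden_cutoff_metrics <- function(scores, status) {
  stopifnot(length(scores) == length(status))
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0L || n0 == 0L) stop_bad_arg("both classes must be present")
  cand <- sort(unique(scores))
  best <- NULL
  for (cut in cand) {
    pos <- scores >= cut
    tp <- sum(pos & status == 1); fp <- sum(pos & status == 0)
    sens <- tp / n1; spec <- 1 - fp / n0
    j <- sens + spec
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(cut = cut, j = j, sens = sens, spec = spec,
                   tp = tp, fp = fp)
  }
  tn <- n0 - best$fp; fn <- n1 - best$tp
  list(cutoff = best$cut,
       sensitivity = best$sens,
       specificity = best$spec,
       accuracy = (best$tp + tn) / (n1 + n0),
       ppv = if (best$tp + best$fp > 0) best$tp / (best$tp + best$fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       tp = best$tp, fp = best$fp, tn = tn, fn = fn)
}

#' Default model-fitting procedure for validation machinery
#'
#' Returns a `fit_fun` suitable for [bootstrap_optimism()] and
#' [split_validate()]: fits `status ~ wgrs_decile + smoking` by logistic
#' regression on the supplied data and predicts the linear predictor on new
#' data.
#'
#' @return A function `data -> (data -> scores)`.
#' @export
grs_smoking_fitter <- function() {
  function(train) {
    fit <- stats::glm(status ~ wgrs_decile + smoking,
                      family = stats::binomial(), data = train)
    function(newdata) as.vector(stats::predict(fit, newdata = newdata))
  }
}
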