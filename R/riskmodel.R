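#' Fit the combined GRS-by-smoking logistic risk model
#'
#' Maximum-likelihood logistic regression of case status on the wGRS decile
#' rank (0-9) and ordinal smoking level (0-2), the two-covariate risk model
#' used for combined genetic/lifestyle assessment.  The wGRS covariate
#' enters as the decile rank by default (`covariate = "decile"`); raw wGRS
#' units are available with `covariate = "wgrs"`.  Additional columns of
#' `scores` (e.g. age group, gender) may be appended via `extra`.
#'
#' @param scores A `grs_scores` data frame (see [score_cohort()]) or any
#'   data frame with columns `status`, `smoking` and the chosen score
#'   column.
#' @param covariate `"decile"` (uses `wgrs_decile`) or `"wgrs"` (raw score).
#' @param extra Character vector of extra covariate columns, if any.
#' @return An object of class `grs_risk_model`: list with `coefficients`
#'   (named: intercept, wgrs, smoking, ...), `or_per_unit`, `ci95` (matrix),
#'   `p_values`, `fitted_probabilities`, `covariate`, and the underlying
#'   `glm` fit.
#' @export
fit_risk_model <- function(scores, covariate = c("decile", "wgrs"),
                           extra = character()) {
  covariate <- match.arg(covariate)
  score_col <- if (covariate == "decile") "wgrs_decile" else "wgrs"
  needed <- c("status", "smoking", score_col, extra)
  missing_cols <- setdiff(needed, names(scores))
  if (length(missing_cols))
    stop_bad_arg("scores lacks column(s): %s", paste(missing_cols, collapse = ", "))
  df <- data.frame(status = scores$status,
                   wgrs = scores[[score_col]],
                   smoking = scores$smoking)
  for (e in extra) df[[e]] <- scores[[e]]
  fml <- stats::as.formula(paste("status ~ wgrs + smoking",
                                 if (length(extra)) paste("+", paste(extra, collapse = " + ")) else ""))
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged)
    stop_bad_arg("logistic fit did not converge (deviance %.4g)", fit$deviance)
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 15))
    stop_bad_arg("fit looks separated: coefficient(s) %s",
                 paste(sprintf("%s=%.3g", names(cf), cf), collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- cbind(low = cf - 1.96 * se, high = cf + 1.96 * se)
  names(cf)[1] <- "intercept"
  rownames(ci)[1] <- "intercept"
  structure(list(coefficients = cf,
                 or_per_unit = exp(cf),
                 ci95 = exp(ci),
                 p_values = summary(fit)$coefficients[, 4],
                 fitted_probabilities = stats::fitted(fit),
                 covariate = covariate,
                 glm_fit = fit),
            class = "grs_risk_model")
}

#' @export
print.grs_risk_model <- function(x, ...) {
  cat("Logistic risk model (status ~ wGRS", if (x$covariate == "decile") "decile" else "raw",
      "+ smoking)\n")
  tab <- data.frame(coef = x$coefficients,
                    OR = x$or_per_unit,
                    ci_low = x$ci95[, 1], ci_high = x$ci95[, 2],
                    p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Relative odds for a covariate combination
#'
#' Evaluates `exp(b0 + b1 * wgrs_decile + b2 * smoking)` for a fitted model
#' (or an explicit coefficient vector), i.e. the odds relative to a
#' hypothetical subject with a zero linear predictor.  With both covariates
#' zero this is `exp(b0)`.
#'
#' @param model A `grs_risk_model`, or a numeric vector
#'   `c(intercept, wgrs, smoking)`.
#' @param wgrs_decile Decile rank 0-9 (or raw wGRS if the model was fitted
#'   on raw scores).
#' @param smoking Smoking level 0-2.
#' @return Relative odds (positive scalar, vectorised over inputs).
#' @export
relative_risk <- function(model, wgrs_decile, smoking) {
  cf <- if (inherits(model, "grs_risk_model")) model$coefficients[1:3] else model
  if (length(cf) != 3L || any(!is.finite(cf)))
    stop_bad_arg("need three finite coefficients (intercept, wgrs, smoking)")
  if (any(smoking < 0 | smoking > 2))
    stop_bad_arg("smoking level must lie in 0..2")
  decile_like <- inherits(model, "grs_risk_model") && model$covariate == "decile" ||
    !inherits(model, "grs_risk_model")
  if (decile_like && any(wgrs_decile < 0 | wgrs_decile > 9))
    stop_bad_arg("wGRS decile must lie in 0..9")
  exp(cf[[1]] + cf[[2]] * wgrs_decile + cf[[3]] * smoking)
}

#' Per-category odds ratios against a reference category
#'
#' For an ordinal (or otherwise ordered) categorisation of subjects, builds
#' the 2x2 table of each category against the reference and returns crude
#' odds ratios with Woolf 95% CIs, together with a p-for-trend from a
#' logistic regression on the ordinal category score.
#'
#' @param status Binary vector (1 = case).
#' @param category Vector of category labels/values, same length.
#' @param reference Reference category (default: first sorted unique value).
#' @return Data frame with columns `category`, `n_cases`, `n_controls`,
#'   `oratio`, `ci_low`, `ci_high`, `p_value` (reference row has OR 1 and NA
#'   CI), plus attribute `p_trend`.  A category empty in either arm gets NA
#'   OR and a flag.
#' @export
category_or_table <- function(status, category, reference = NULL) {
  stopifnot(length(status) == length(category))
  lev <- if (is.factor(category)) levels(category) else sort(unique(category))
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) stop_bad_arg("reference category not present")
  rc <- sum(status == 1 & category == reference)
  rn <- sum(status == 0 & category == reference)
  if (rc == 0 || rn == 0)
    stop_bad_arg("reference category empty in cases or controls")
  rows <- lapply(lev, function(g) {
    a <- sum(status == 1 & category == g)
    b <- sum(status == 0 & category == g)
    if (identical(g, reference))
      return(data.frame(category = as.character(g), n_cases = a, n_controls = b,
                        oratio = 1, ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, empty = FALSE))
    if (a + b == 0)
      return(data.frame(category = as.character(g), n_cases = 0L, n_controls = 0L,
                        oratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, empty = TRUE))
    orr <- or_2x2(a, rc, b, rn)  # odds of being in g vs reference, cases over controls
    data.frame(category = as.character(g), n_cases = a, n_controls = b,
               oratio = orr$oratio, ci_low = orr$ci95[1], ci_high = orr$ci95[2],
               p_value = orr$p_value, empty = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # trend test: logistic on the ordinal rank of the category
  score <- match(as.character(category), as.character(lev)) - 1
  fit <- stats::glm(status ~ score, family = stats::binomial())
  attr(out, "p_trend") <- summary(fit)$coefficients["score", 4]
  out
}
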