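#' Pipeline configuration
#'
#' Everything the end-to-end run needs: SNP definitions, wGRS mode, decile
#' reference policy, bootstrap replicate count, split fraction and seed.
#' Serialisable to/from JSON with the same key names.
#'
#' @param snps SNP panel used for weighting; `NULL` means estimate
#'   frequencies and odds ratios from the input cohort itself.
#' @param grs_mode `"normalized"` or `"literal"` (see
#'   [snp_genotype_scores()]).
#' @param decile_reference `"controls"` or `"pooled"`.
#' @param bootstrap_B Bootstrap replicates for optimism correction and AUC
#'   CIs.
#' @param split_fraction Training fraction for split validation.
#' @param seed Integer seed for every stochastic step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(snps = NULL,
                            grs_mode = c("normalized", "literal"),
                            decile_reference = c("controls", "pooled"),
                            bootstrap_B = 1000,
                            split_fraction = 0.75,
                            seed = 1) {
  grs_mode <- match.arg(grs_mode)
  decile_reference <- match.arg(decile_reference)
  stopifnot(bootstrap_B >= 1, split_fraction > 0, split_fraction < 1)
  structure(list(snps = snps, grs_mode = grs_mode,
                 decile_reference = decile_reference,
                 bootstrap_B = as.integer(bootstrap_B),
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with the [pipeline_config()] keys.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  snps <- NULL
  if (!is.null(raw$snps))
    snps <- do.call(snp_panel, lapply(seq_len(nrow(raw$snps)), function(i)
      snp_def(raw$snps$snp_id[i], raw$snps$risk_allele[i] %||% "B",
              raw$snps$p[i], raw$snps$oratio[i])))
  pipeline_config(snps = snps,
                  grs_mode = raw$grs_mode %||% "normalized",
                  decile_reference = raw$decile_reference %||% "controls",
                  bootstrap_B = raw$bootstrap_B %||% 1000,
                  split_fraction = raw$split_fraction %||% 0.75,
                  seed = raw$seed %||% 1)
}

config_hash <- function(config) {
  ser <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 12,
                          null = "null")
  fnv1a32(as.character(ser))
}

#' Run the full association-to-validation pipeline
#'
#' Reads a cohort, then writes in order: the per-SNP association table, the
#' SNP weight table, per-subject scores, the category odds-ratio tables
#' (cGRS bands, wGRS deciles, smoking), the fitted risk model, and the
#' evaluation report (AUCs with bootstrap CIs, wGRS vs cGRS comparison,
#' Hosmer-Lemeshow, bootstrap-optimism-corrected AUC, split validation,
#' Youden cutoff metrics).  Every artifact is stamped with the
#' configuration hash and seed; a rerun with identical inputs is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param cohort_path Path to a cohort TSV (see [read_cohort()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, cohort_path, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- read_cohort(cohort_path)
  if (!is.null(config$snps)) {
    absent <- setdiff(config$snps$snp_id, attr(cohort, "snp_ids"))
    if (length(absent))
      stop_bad_arg("cohort %s lacks configured SNP column(s): %s",
                   cohort_path, paste(absent, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# config_hash=%s seed=%d", config_hash(config), config$seed)
  paths <- list()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(stamp, con)
    writer(con)
    paths[[name]] <<- path
  }
  tsv <- function(df) function(con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  kv <- function(x) function(con)
    writeLines(sprintf("%s\t%s", names(x),
                       vapply(x, function(v) format(v, digits = 10),
                              character(1))), con)

  log_lines <- c(stamp,
                 sprintf("grs_mode\t%s", config$grs_mode),
                 sprintf("decile_reference\t%s", config$decile_reference),
                 sprintf("ci_method\tWoolf"),
                 sprintf("auc_ci\tbootstrap percentile B=%d", config$bootstrap_B),
                 sprintf("weights\t%s",
                         if (is.null(config$snps)) "estimated from cohort"
                         else "from configured panel"))

  ## 1. association table
  assoc <- assoc_table(cohort)
  emit("assoc_table.tsv", tsv(format_num_df(assoc)))

  ## 2. weights + 3. scores
  scores <- score_cohort(cohort, snps = config$snps, mode = config$grs_mode,
                         decile_reference = config$decile_reference)
  emit("snp_weights.tsv", tsv(format_num_df(attr(scores, "weights"))))
  emit("scores.tsv", tsv(format_num_df(
    as.data.frame(scores)[, c("subject_id", "status", "cgrs", "wgrs",
                              "wgrs_decile")])))

  ## 4. category OR tables
  for (spec in list(c("cgrs_band_or.tsv", "cgrs_band"),
                    c("wgrs_decile_or.tsv", "wgrs_decile"),
                    c("smoking_or.tsv", "smoking"))) {
    tab <- category_or_table(scores$status, scores[[spec[2]]])
    tab$p_trend <- attr(tab, "p_trend")
    emit(spec[1], tsv(format_num_df(tab)))
  }

  ## 5. model fit
  model <- fit_risk_model(scores)
  cf <- model$coefficients
  fit_out <- c(stats::setNames(as.list(cf), paste0("coef_", names(cf))),
               stats::setNames(as.list(model$or_per_unit),
                               paste0("or_", names(cf))))
  emit("model_fit.txt", kv(fit_out))

  ## 6. evaluation report
  lp <- as.vector(cf[1] + cf[2] * scores$wgrs_decile + cf[3] * scores$smoking)
  auc_full <- auc_rank(lp, scores$status, ci = TRUE, B = config$bootstrap_B,
                       seed = config$seed)
  auc_w <- auc_rank(scores$wgrs, scores$status)
  auc_c <- auc_rank(scores$cgrs, scores$status)
  auc_s <- auc_rank(scores$smoking, scores$status)
  cmp <- compare_auc(scores$wgrs, scores$cgrs, scores$status,
                     B = config$bootstrap_B, seed = config$seed)
  hl <- hosmer_lemeshow(model$fitted_probabilities, scores$status)
  sdf <- as.data.frame(scores)
  boc <- bootstrap_optimism(sdf, grs_smoking_fitter(),
                            B = config$bootstrap_B, seed = config$seed)
  sv <- split_validate(sdf, grs_smoking_fitter(),
                       train_fraction = config$split_fraction,
                       seed = config$seed)
  yc <- youden_cutoff_metrics(lp, scores$status)
  report <- list(auc_full = auc_full$auc,
                 auc_full_ci_low = auc_full$ci95[1],
                 auc_full_ci_high = auc_full$ci95[2],
                 auc_full_boc = boc$auc_corrected,
                 optimism = boc$optimism,
                 auc_wgrs = auc_w$auc, auc_cgrs = auc_c$auc,
                 auc_smoking = auc_s$auc,
                 p_wgrs_vs_cgrs = cmp$p_value,
                 hl_statistic = hl$statistic, hl_p = hl$p_value,
                 c_train = sv$c_train, c_test = sv$c_test,
                 cutoff = yc$cutoff, sensitivity = yc$sensitivity,
                 specificity = yc$specificity, accuracy = yc$accuracy,
                 ppv = yc$ppv, npv = yc$npv)
  emit("eval_report.txt", kv(report))

  emit("run_log.txt", function(con) writeLines(log_lines[-1], con))
  invisible(paths)
}

## format numeric columns to a fixed significant-digit text form so reruns
## are byte-identical across platforms
format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- format(df[[j]], digits = 10)
  df
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `expand-counts`, `assoc`, `score`, `fit`,
#' `evaluate`, `validate`, `run`.  Common flags: `--config <json>`,
#' `--seed <int>`, `--out <dir>`, `--cohort <tsv>`.  Invoke from a script
#' as `grsrisk::grs_cli()`.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status 0 invisibly on success; stops on error.
#' @export
grs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: grsrisk <simulate|expand-counts|assoc|score|fit|evaluate|validate|run>",
        "[--config F] [--cohort F] [--counts F] [--seed N] [--out DIR]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- parse_flags(args[-1L])
  out_dir <- opt$out %||% "."
  seed <- as.integer(opt$seed %||% 1L)
  pcfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
          else pipeline_config(seed = seed)
  if (!is.null(opt$seed)) pcfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  need_cohort <- function() {
    if (is.null(opt$cohort)) stop_bad_arg("%s requires --cohort", cmd)
    read_cohort(opt$cohort)
  }
  switch(cmd,
    "simulate" = {
      scfg <- if (!is.null(opt$config)) read_sim_config(opt$config)
              else sim_config(seed = seed)
      if (!is.null(opt$seed)) scfg$seed <- seed
      write_cohort(simulate_cohort(scfg), file.path(out_dir, "cohort.tsv"))
    },
    "expand-counts" = {
      if (is.null(opt$counts)) stop_bad_arg("expand-counts requires --counts")
      tab <- utils::read.delim(opt$counts, sep = "\t",
                               stringsAsFactors = FALSE)
      df <- expand_counts(tab)
      utils::write.table(df, file.path(out_dir, "expanded.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    "assoc" = {
      write_assoc_table(assoc_table(need_cohort()),
                        file.path(out_dir, "assoc_table.tsv"))
    },
    "score" = {
      scores <- score_cohort(need_cohort(), snps = pcfg$snps,
                             mode = pcfg$grs_mode,
                             decile_reference = pcfg$decile_reference)
      utils::write.table(
        as.data.frame(scores)[, c("subject_id", "status", "cgrs", "wgrs",
                                  "wgrs_decile")],
        file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    },
    "fit" = ,
    "evaluate" = ,
    "validate" = ,
    "run" = {
      if (is.null(opt$cohort)) stop_bad_arg("%s requires --cohort", cmd)
      run_pipeline(pcfg, opt$cohort, out_dir)
    },
    stop_bad_arg("unknown subcommand: %s", cmd)
  )
  invisible(0L)
}

parse_flags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args))
      stop_bad_arg("malformed arguments near '%s'", a)
    opt[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opt
}

#' Relative-risk calculator for the CLI
#'
#' Convenience wrapper: evaluates [relative_risk()] for coefficients read
#' from a `model_fit.txt` artifact written by [run_pipeline()].
#'
#' @param model_path Path to `model_fit.txt`.
#' @param wgrs_decile Decile rank 0-9.
#' @param smoking Smoking level 0-2.
#' @return Relative odds versus the zero-covariate baseline.
#' @export
relative_risk_from_file <- function(model_path, wgrs_decile, smoking) {
  lines <- readLines(model_path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- strsplit(lines, "\t")
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                          vapply(kv, `[`, character(1), 1))
  relative_risk(c(vals[["coef_intercept"]], vals[["coef_wgrs"]],
                  vals[["coef_smoking"]]), wgrs_decile, smoking)
}
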