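#' Individual-level case-control cohort
#'
#' A cohort is a `data.frame` with mandatory columns `subject_id` (unique
#' labels), `status` (0 = control, 1 = case), `smoking` (ordinal 0 = never,
#' 1 = light, 2 = heavy) and one column per SNP holding the risk-allele
#' dosage 0/1/2 or `NA` for a failed genotype call.  The SNP column names
#' are recorded in the `snp_ids` attribute.
#'
#' @param df Data frame with the columns above.
#' @param snp_ids Character vector naming the dosage columns; defaults to
#'   every column after the three mandatory ones.
#' @return A validated `grs_cohort` object.
#' @export
as_cohort <- function(df, snp_ids = NULL) {
  stopifnot(is.data.frame(df))
  mandatory <- c("subject_id", "status", "smoking")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop_bad_arg("cohort is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  if (is.null(snp_ids)) snp_ids <- setdiff(names(df), mandatory)
  out <- df[, c(mandatory, snp_ids), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("grs_cohort", "data.frame")
  attr(out, "snp_ids") <- snp_ids
  validate_cohort(out)
  out
}

validate_cohort <- function(cohort) {
  if (anyDuplicated(cohort$subject_id)) {
    dup <- cohort$subject_id[duplicated(cohort$subject_id)][1L]
    stop_bad_arg("duplicate subject_id: %s", dup)
  }
  bad <- which(!cohort$status %in% c(0L, 1L))
  if (length(bad))
    stop_bad_arg("status must be 0/1; offending subject %s (row %d)",
                 cohort$subject_id[bad[1L]], bad[1L])
  bad <- which(!cohort$smoking %in% c(0L, 1L, 2L))
  if (length(bad))
    stop_bad_arg("smoking must be 0/1/2; offending subject %s (row %d)",
                 cohort$subject_id[bad[1L]], bad[1L])
  for (s in attr(cohort, "snp_ids")) {
    d <- cohort[[s]]
    bad <- which(!is.na(d) & !d %in% c(0L, 1L, 2L))
    if (length(bad))
      stop_bad_arg("dosage must be 0/1/2/NA; offending subject %s, SNP %s",
                   cohort$subject_id[bad[1L]], s)
  }
  invisible(cohort)
}

#' @export
print.grs_cohort <- function(x, ...) {
  cat(sprintf("grs_cohort: %d subjects (%d cases / %d controls), %d SNPs\n",
              nrow(x), sum(x$status == 1), sum(x$status == 0),
              length(attr(x, "snp_ids"))))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Dosage columns of a cohort
#' @param cohort A `grs_cohort`.
#' @return Integer matrix, subjects x SNPs (may contain `NA`).
#' @export
dosage_matrix <- function(cohort) {
  snp_ids <- attr(cohort, "snp_ids")
  m <- as.matrix(as.data.frame(cohort)[, snp_ids, drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Expand a printed contingency table into individual records
#'
#' Published tables report category-level case/control counts; this
#' materialises them as one row per subject so the generic 2x2 and AUC
#' machinery can be applied to printed data.  Row order (and therefore
#' subject ids) is deterministic: categories in input order, cases before
#' controls within a category.
#'
#' @param table Data frame with columns `label`, `cases`, `controls`
#'   (non-negative integers), one row per category.
#' @param category Name for the category column in the output.
#' @param values Optional vector of category values (default: the labels);
#'   e.g. `0:2` to code never/light/heavy smoking ordinally.
#' @return Data frame with columns `subject_id`, `status` and the category
#'   column; `sum(cases)` cases followed by controls within each category.
#' @examples
#' expand_counts(data.frame(label = "x", cases = 2, controls = 3))
#' @export
expand_counts <- function(table, category = "category", values = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) {
    out <- data.frame(subject_id = character(), status = integer())
    out[[category]] <- character()
    return(out)
  }
  stopifnot(all(c("label", "cases", "controls") %in% names(table)))
  if (!is_count_vec(table$cases) || !is_count_vec(table$controls))
    stop_bad_arg("case and control counts must be non-negative integers")
  if (is.null(values)) values <- table$label
  stopifnot(length(values) == nrow(table))
  n <- table$cases + table$controls
  status <- unlist(lapply(seq_len(nrow(table)), function(i)
    rep(c(1L, 0L), c(table$cases[i], table$controls[i]))), use.names = FALSE)
  value <- rep(values, n)
  out <- data.frame(subject_id = sprintf("S%05d", seq_along(status)),
                    status = status, stringsAsFactors = FALSE)
  out[[category]] <- value
  out
}

#' Read / write a cohort as tab-separated text
#'
#' The on-disk format is TSV with header
#' `subject_id status smoking <snp_id>...`; missing dosages are written as
#' `NA`.  `read_cohort(write_cohort(x))` round-trips exactly, including
#' missing markers.
#'
#' @param path File path.
#' @param cohort A `grs_cohort`.
#' @return `read_cohort` returns a validated `grs_cohort`; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "NA")
  mandatory <- c("subject_id", "status", "smoking")
  if (!identical(names(df)[seq_len(3)], mandatory))
    stop_bad_arg("%s: header must start with 'subject_id\tstatus\tsmoking'", path)
  df$subject_id <- as.character(df$subject_id)
  tryCatch(as_cohort(df),
           error = function(e) stop_bad_arg("%s: %s", path, conditionMessage(e)))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
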