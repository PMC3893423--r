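#' Run the full validation pipeline on a cohort
#'
#' Convenience wrapper chaining the pipeline stages: phenotype the
#' questionnaire, classify diabetes type, build the three administrative
#' criterion standards, cross-tabulate, and compute agreement statistics.
#'
#' @param cohort a `dm_cohort` (from [read_cohort()] or
#'   [simulate_cohort()]).
#' @param lexicons lexicon list, see [default_lexicons()].
#' @param config a [window_config()].
#' @return a list of class `dm_validation` with elements `assignments`
#'   (typed), `criteria` (named list of criterion data frames),
#'   `tables` (named list of [confusion_table()]s), `stats` (named list
#'   of [agreement_stats()]), `type_table` (the [type_crosstab()]) and
#'   `prevalence`.
#' @export
run_validation <- function(cohort, lexicons = default_lexicons(),
                           config = window_config()) {
  stopifnot(inherits(cohort, "dm_cohort"))
  assignments <- phenotype_cohort(cohort$questionnaire, lexicons)
  typed <- type_cohort(assignments, cohort$questionnaire)
  criteria <- list(
    apdc = apdc_criterion(cohort, typed, config),
    mbs = mbs_criterion(cohort, typed, config),
    pbs = pbs_criterion(cohort, typed, config)
  )
  labels <- c(
    apdc = "hospital diabetes diagnosis code (APDC)",
    mbs = sprintf("at least %d HbA1c test claim(s) %d-%d (MBS)",
                  config$hba1c_min_claims, config$hba1c_years[1],
                  config$hba1c_years[2]),
    pbs = "diabetes medication dispensing claim in look-back year (PBS)"
  )
  tables <- lapply(names(criteria), function(s) {
    build_confusion(typed, criteria[[s]], label = labels[[s]])
  })
  names(tables) <- names(criteria)
  stats <- lapply(tables, agreement_stats)
  structure(list(
    assignments = typed,
    criteria = criteria,
    tables = tables,
    stats = stats,
    type_table = type_crosstab(typed, criteria$apdc),
    prevalence = attr(assignments, "prevalence")
  ), class = "dm_validation")
}

#' @export
print.dm_validation <- function(x, ...) {
  cat(sprintf("Reported diabetes prevalence: %.2f%%\n\n",
              100 * x$prevalence))
  for (s in names(x$stats)) {
    print(x$tables[[s]])
    print(x$stats[[s]])
    cat("\n")
  }
  print(x$type_table)
  invisible(x)
}

fmt_pct1 <- function(p) ifelse(is.na(p), "undefined",
                               sprintf("%.1f", 100 * p))

report_block <- function(tbl, st) {
  c(sprintf("== %s ==", tbl$label %||% "criterion standard"),
    sprintf("%-26s %12s %12s %12s", "self-report", "criterion+",
            "criterion-", "total"),
    sprintf("%-26s %12d %12d %12d", "diabetes", tbl$tp, tbl$fp,
            tbl$tp + tbl$fp),
    sprintf("%-26s %12d %12d %12d", "non-diabetes", tbl$fn, tbl$tn,
            tbl$fn + tbl$tn),
    sprintf("%-26s %12d %12d %12d", "total", tbl$tp + tbl$fn,
            tbl$fp + tbl$tn, tbl$tp + tbl$fp + tbl$fn + tbl$tn),
    sprintf("%-26s %12d %12d %12d", "uncertain*", tbl$uncertain_pos,
            tbl$uncertain_neg, tbl$uncertain_pos + tbl$uncertain_neg),
    sprintf("sensitivity %s%%  specificity %s%%  PPV %s%%  NPV %s%%  kappa %s",
            fmt_pct1(st$sensitivity), fmt_pct1(st$specificity),
            fmt_pct1(st$ppv), fmt_pct1(st$npv),
            ifelse(is.na(st$kappa), "undefined",
                   sprintf("%.2f", st$kappa))),
    "")
}

#' Write a plain-text validation report and a statistics CSV
#'
#' Renders each criterion standard as a 2x2 count block (with the
#' separately analysed uncertain row) followed by its agreement
#' statistics — percentages to one decimal place, kappa to two — in the
#' order the results are supplied, plus the type cross-tabulation when
#' present. A machine-readable CSV of the raw (unrounded) statistics can
#' be written alongside.
#'
#' @param results a `dm_validation` from [run_validation()], or any list
#'   with `tables` ([confusion_table()]s), `stats`
#'   ([agreement_stats()]) and optionally `type_table`.
#' @param path output path of the text report.
#' @param stats_csv optional path for the statistics CSV.
#' @return invisibly, `path`.
#' @export
write_validation_report <- function(results, path, stats_csv = NULL) {
  if (length(results$tables) == 0) {
    stop("results must contain at least one confusion table")
  }
  lines <- character(0)
  for (s in names(results$tables)) {
    lines <- c(lines, report_block(results$tables[[s]], results$stats[[s]]))
  }
  if (!is.null(results$type_table)) {
    ct <- results$type_table$counts
    lines <- c(lines, "== diabetes type vs hospital-record type ==",
               paste(c(sprintf("%-20s", "algorithm type"),
                       sprintf("%18s", colnames(ct))), collapse = ""))
    for (r in rownames(ct)) {
      lines <- c(lines, paste(c(sprintf("%-20s", r),
                                sprintf("%18d", ct[r, ])), collapse = ""))
    }
    lines <- c(lines, sprintf(
      "row agreement: %s",
      paste(names(results$type_table$row_agreement),
            paste0(fmt_pct1(results$type_table$row_agreement), "%"),
            sep = " = ", collapse = ", ")), "")
  }
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write report to ", path)

  if (!is.null(stats_csv)) {
    rows <- lapply(names(results$stats), function(s) {
      st <- results$stats[[s]]
      tbl <- results$tables[[s]]
      data.frame(source = s, tp = tbl$tp, fp = tbl$fp, fn = tbl$fn,
                 tn = tbl$tn, uncertain_pos = tbl$uncertain_pos,
                 uncertain_neg = tbl$uncertain_neg,
                 sensitivity = st$sensitivity, specificity = st$specificity,
                 ppv = st$ppv, npv = st$npv, p_o = st$p_o, p_e = st$p_e,
                 kappa = st$kappa, stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), stats_csv, row.names = FALSE)
  }
  invisible(path)
}
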