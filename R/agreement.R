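#' Construct a 2x2 confusion table
#'
#' Rows are the self-report groups (diabetes / non-diabetes), columns the
#' criterion standard (positive / negative). Participants of uncertain
#' status never enter the 2x2; their criterion counts are carried
#' alongside as a separate row.
#'
#' @param tp,fp,fn,tn non-negative cell counts: self-report diabetes with
#'   positive / negative criterion, and self-report non-diabetes with
#'   positive / negative criterion.
#' @param uncertain_pos,uncertain_neg criterion-positive / -negative
#'   counts among uncertain-status participants.
#' @param label optional label describing the criterion standard.
#' @return an object of class `confusion_table`.
#' @export
#' @examples
#' confusion_table(15143, 3943, 2904, 169983, 557, 596)
confusion_table <- function(tp, fp, fn, tn, uncertain_pos = 0,
                            uncertain_neg = 0, label = NULL) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn,
             uncertain_pos = uncertain_pos, uncertain_neg = uncertain_neg)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("confusion table cells must be non-negative counts")
  }
  if (tp + fp + fn + tn <= 0) {
    stop("confusion table must contain at least one observation")
  }
  structure(as.list(c(cells, label = list(label))), class = "confusion_table")
}

#' Cross-tabulate self-report against a criterion standard
#'
#' Restricts to participants included in the criterion's analysis subset,
#' tabulates the diabetes and non-diabetes self-report groups against the
#' binary criterion, and tabulates uncertain-status participants
#' separately.
#'
#' @param assignments assignments from [phenotype_cohort()].
#' @param criterion a criterion data frame from [apdc_criterion()],
#'   [mbs_criterion()] or [pbs_criterion()].
#' @param label optional label for reports.
#' @return a [confusion_table()].
#' @export
build_confusion <- function(assignments, criterion, label = NULL) {
  idx <- match(criterion$participant_id, assignments$participant_id)
  if (anyNA(idx)) {
    stop("criterion contains participants without a phenotype assignment")
  }
  status <- assignments$status[idx]
  if (!all(status %in% STATUS_LEVELS)) {
    stop("assignments carry a status outside {diabetes, non_diabetes, uncertain}")
  }
  inc <- criterion$included
  pos <- criterion$criterion_positive
  confusion_table(
    tp = sum(inc & status == "diabetes" & pos),
    fp = sum(inc & status == "diabetes" & !pos),
    fn = sum(inc & status == "non_diabetes" & pos),
    tn = sum(inc & status == "non_diabetes" & !pos),
    uncertain_pos = sum(inc & status == "uncertain" & pos),
    uncertain_neg = sum(inc & status == "uncertain" & !pos),
    label = label %||% unique(criterion$source)[1]
  )
}

#' Agreement statistics from a 2x2 table
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive
#' predictive value `tp/(tp+fp)`, negative predictive value `tn/(fn+tn)`,
#' observed agreement, chance-expected agreement from the marginals, and
#' the two-rater kappa `(p_o - p_e) / (1 - p_e)` (the two-rater case of
#' the Fleiss formulation, equal to Cohen's kappa; no continuity
#' correction). A statistic whose denominator is zero is reported as `NA`
#' (undefined), never as 0.
#'
#' @param x a [confusion_table()].
#' @return an object of class `agreement_stats`: a list with elements
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `p_o`, `p_e`, `kappa`
#'   and `n`.
#' @export
#' @examples
#' agreement_stats(confusion_table(15143, 3943, 2904, 169983))
agreement_stats <- function(x) {
  stopifnot(inherits(x, "confusion_table"))
  # doubles: marginal products overflow 32-bit integers at cohort scale
  tp <- as.numeric(x$tp); fp <- as.numeric(x$fp)
  fn <- as.numeric(x$fn); tn <- as.numeric(x$tn)
  n <- tp + fp + fn + tn
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  structure(list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, fp + tn),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, fn + tn),
    p_o = p_o,
    p_e = p_e,
    kappa = if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_,
    n = n,
    label = x$label
  ), class = "agreement_stats")
}

#' @export
print.confusion_table <- function(x, ...) {
  if (!is.null(x$label)) cat("Criterion standard:", x$label, "\n")
  m <- matrix(c(x$tp, x$fp, x$tp + x$fp,
                x$fn, x$tn, x$fn + x$tn,
                x$tp + x$fn, x$fp + x$tn, x$tp + x$fp + x$fn + x$tn),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("self-report diabetes",
                                "self-report non-diabetes", "total"),
                              c("criterion+", "criterion-", "total")))
  print(m)
  cat(sprintf("uncertain (analysed separately): %d criterion+, %d criterion-\n",
              x$uncertain_pos, x$uncertain_neg))
  invisible(x)
}

#' @export
print.agreement_stats <- function(x, ...) {
  if (!is.null(x$label)) cat("Criterion standard:", x$label, "\n")
  pct <- function(p) if (is.na(p)) "undefined" else sprintf("%.1f%%", 100 * p)
  cat(sprintf("  sensitivity %s  specificity %s\n",
              pct(x$sensitivity), pct(x$specificity)))
  cat(sprintf("  PPV %s  NPV %s\n", pct(x$ppv), pct(x$npv)))
  cat(sprintf("  kappa %s  (observed %s, chance-expected %s; n = %.0f)\n",
              if (is.na(x$kappa)) "undefined" else sprintf("%.2f", x$kappa),
              pct(x$p_o), pct(x$p_e), x$n))
  invisible(x)
}

#' Cross-tabulate algorithm type against hospital-record type
#'
#' Restricted to diabetes-group participants included in the
#' hospital-data comparison: rows are the algorithm's type labels,
#' columns the hospital-record type, and the row agreement is the
#' diagonal cell over the row total (`type1` vs `type1`, `type2` vs
#' `type2`, `gestational_other` vs `gestational_other`).
#'
#' @param typed typed assignments from [type_cohort()].
#' @param criterion hospital criterion data frame from [apdc_criterion()]
#'   (carries the `apdc_type` column).
#' @return an object of class `type_crosstab`: a list with the 3x5 count
#'   matrix `counts` and the named vector `row_agreement`.
#' @export
type_crosstab <- function(typed, criterion) {
  idx <- match(criterion$participant_id, typed$participant_id)
  if (anyNA(idx)) stop("criterion contains participants without assignments")
  keep <- criterion$included & typed$status[idx] == "diabetes"
  algo <- factor(typed$diabetes_type[idx][keep], levels = TYPE_LEVELS[1:3])
  hosp <- factor(criterion$apdc_type[keep], levels = APDC_TYPE_LEVELS[1:5])
  counts <- table(algorithm = algo, hospital = hosp)
  diag_cells <- c(type1 = counts["type1", "type1"],
                  type2 = counts["type2", "type2"],
                  gestational_other = counts["gestational_other",
                                             "gestational_other"])
  totals <- rowSums(counts)
  row_agreement <- ifelse(totals > 0, diag_cells / totals, NA_real_)
  structure(list(counts = counts, row_agreement = row_agreement),
            class = "type_crosstab")
}

#' @export
print.type_crosstab <- function(x, ...) {
  print(x$counts)
  pct <- ifelse(is.na(x$row_agreement), "undefined",
                sprintf("%.1f%%", 100 * x$row_agreement))
  cat("row agreement:", paste(names(x$row_agreement), pct, sep = " = ",
                              collapse = ", "), "\n")
  invisible(x)
}
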