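#' Classify a free-text illness response
#'
#' Matches free text from the "other important illness" questionnaire field
#' against the diagnosis lexicon. Matching is case-insensitive,
#' whitespace-normalised and whole-phrase (word boundaries), so "diabetes"
#' does not fire inside "diabetic" but does fire as a word inside longer
#' phrases. Uncertain terms take precedence over positive terms: a response
#' of "diabetes insipidus" is routed to `uncertain` even though it contains
#' the positive word "diabetes".
#'
#' @param text character vector of free-text responses (may be empty or
#'   `NA`).
#' @param lexicon a `diagnosis_lexicon`, see [read_diagnosis_lexicon()].
#' @return character vector with values `"diabetes"`, `"uncertain"` or
#'   `"none"`.
#' @export
#' @examples
#' lex <- read_diagnosis_lexicon()
#' match_free_text_diagnosis(c("sugar diabetes", "diabetes insipidus",
#'                             "hypertension", ""), lex)
match_free_text_diagnosis <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "diagnosis_lexicon"))
  unc <- match_terms(text, lexicon$term[lexicon$category == "uncertain"])
  pos <- match_terms(text, lexicon$term[lexicon$category == "diabetes"])
  out <- rep("none", length(text))
  out[rowSums(pos) > 0] <- "diabetes"
  out[rowSums(unc) > 0] <- "uncertain"  # precedence over positive terms
  out
}

#' Detect diabetes medication in questionnaire medication fields
#'
#' Searches the free-text medication field for insulin products and oral
#' hypoglycaemic agents using the medication lexicon, and combines the
#' result with the dedicated metformin-product tick box.
#'
#' @param text character vector of medication free text.
#' @param metformin_tickbox logical vector: the tick box for the
#'   metformin-based products (Diabex / Diaformin / Metformin).
#' @param lexicon a `medication_lexicon`, see [read_medication_lexicon()].
#' @return a data frame with columns `insulin` (any insulin-class match),
#'   `oha` (tick box set, or any OHA-class match) and `classes` (list
#'   column of the distinct medication classes matched, including
#'   `"biguanide"` when the tick box is set).
#' @export
match_medication_text <- function(text, metformin_tickbox, lexicon) {
  stopifnot(inherits(lexicon, "medication_lexicon"))
  n <- max(length(text), length(metformin_tickbox))
  text <- rep_len(text, n)
  metformin_tickbox <- rep_len(as.logical(metformin_tickbox), n)
  metformin_tickbox[is.na(metformin_tickbox)] <- FALSE

  hits <- match_terms(text, lexicon$term)
  classes <- lapply(seq_len(n), function(i) {
    cl <- unique(lexicon$class[hits[i, ]])
    if (metformin_tickbox[i]) cl <- unique(c(cl, "biguanide"))
    sort(cl)
  })
  insulin <- vapply(classes, function(cl) "insulin" %in% cl, logical(1))
  oha <- vapply(classes, function(cl) any(cl %in% OHA_CLASSES), logical(1))
  data.frame(insulin = insulin, oha = oha,
             classes = I(classes), stringsAsFactors = FALSE)
}

# Vectorised core of the status algorithm; returns the assignment table.
phenotype_core <- function(q, lexicons) {
  n <- nrow(q)
  tick <- !is.na(q$diabetes_tickbox) & q$diabetes_tickbox
  text_match <- match_free_text_diagnosis(q$other_illness_text,
                                          lexicons$diagnosis)
  meds <- match_medication_text(q$medication_text, q$metformin_tickbox,
                                lexicons$medication)

  status <- rep("non_diabetes", n)
  evidence <- rep("none", n)

  # (1) tick box outranks everything
  status[tick] <- "diabetes"
  evidence[tick] <- "tickbox"

  # (2) free text, searched only among non-tickers
  ft_diab <- !tick & text_match == "diabetes"
  ft_unc <- !tick & text_match == "uncertain"
  status[ft_diab] <- "diabetes"
  evidence[ft_diab] <- "free_text"
  status[ft_unc] <- "uncertain"
  evidence[ft_unc] <- "free_text"

  # (3) medication fields for the remainder: insulin adds to the diabetes
  # group, OHA-only use is uncertain
  rest <- !tick & text_match == "none"
  ins <- rest & meds$insulin
  oha_only <- rest & !meds$insulin & meds$oha
  status[ins] <- "diabetes"
  evidence[ins] <- "insulin_text"
  status[oha_only] <- "uncertain"
  evidence[oha_only] <- "oha_text"

  data.frame(
    participant_id = q$participant_id,
    status = status,
    evidence = evidence,
    self_reported_insulin = meds$insulin,
    self_reported_oha = meds$oha,
    diabetes_type = ifelse(status == "diabetes", NA_character_,
                           "not_applicable"),
    stringsAsFactors = FALSE
  )
}

#' Assign diabetes status to a single questionnaire record
#'
#' Single-record interface to the status algorithm; see
#' [phenotype_cohort()] for the evaluation order.
#'
#' @param record a one-row questionnaire data frame.
#' @param lexicons list with elements `medication` and `diagnosis`, see
#'   [default_lexicons()].
#' @return a one-row assignment data frame.
#' @export
assign_status <- function(record, lexicons = default_lexicons()) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  phenotype_core(record, lexicons)
}

#' Assign diabetes status across a cohort
#'
#' Applies the rule-based status algorithm to every baseline questionnaire
#' record. Evaluation order per participant: (1) an affirmative diabetes
#' tick box assigns `diabetes` with evidence `tickbox`; (2) otherwise the
#' free-text illness field is matched against the diagnosis lexicon
#' (positive terms assign `diabetes`, uncertain terms assign `uncertain`);
#' (3) otherwise the medication fields are searched: any insulin product
#' assigns `diabetes`, oral hypoglycaemic agents alone assign `uncertain`;
#' (4) otherwise `non_diabetes`. Self-reported insulin and OHA indicators
#' are recorded for every participant regardless of the path taken.
#'
#' @param questionnaire validated questionnaire data frame (see
#'   [read_cohort()]).
#' @param lexicons list with elements `medication` and `diagnosis`.
#' @return a data frame of assignments (columns `participant_id`,
#'   `status`, `evidence`, `self_reported_insulin`, `self_reported_oha`,
#'   `diabetes_type`), with attributes `counts` (participants entering via
#'   each evidence path) and `prevalence` (diabetes-group fraction;
#'   `NA` for an empty cohort).
#' @export
phenotype_cohort <- function(questionnaire, lexicons = default_lexicons()) {
  out <- phenotype_core(questionnaire, lexicons)
  counts <- table(factor(out$evidence, levels = EVIDENCE_LEVELS),
                  factor(out$status, levels = STATUS_LEVELS))
  n <- nrow(out)
  prevalence <- if (n == 0) NA_real_ else sum(out$status == "diabetes") / n
  if (n == 0) warning("empty cohort: prevalence undefined")
  attr(out, "counts") <- counts
  attr(out, "prevalence") <- prevalence
  log_stage("phenotype_cohort", n,
            c(uncertain = sum(out$status == "uncertain")),
            sum(out$status != "uncertain"))
  out
}

#' Reported prevalence from evidence-path counts
#'
#' Combines the component counts of the status algorithm (tick box,
#' free-text and insulin-only entrants to the diabetes group) into the
#' reported prevalence over the full cohort.
#'
#' @param tickbox,free_text,insulin counts entering the diabetes group via
#'   each evidence path.
#' @param cohort_size total number of participants.
#' @return the prevalence as a proportion.
#' @export
#' @examples
#' reported_prevalence(23981, 119, 58, 266848)  # 0.0905...
reported_prevalence <- function(tickbox, free_text, insulin, cohort_size) {
  stopifnot(cohort_size > 0)
  (tickbox + free_text + insulin) / cohort_size
}
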