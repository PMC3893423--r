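#' Detect a declared diabetes type in free text
#'
#' Scans an illness free-text response for an explicit statement of the
#' diabetes type ("type 1 diabetes", "diabetes type 2", "grade 2
#' diabetes", ...). Used by the typing algorithm, which gives an explicit
#' declaration precedence over the medication/age rules.
#'
#' @param text character vector.
#' @return character vector with values `"type1"`, `"type2"` or `"none"`.
#' @export
detect_declared_type <- function(text) {
  text <- normalise_text(text)
  t1 <- grepl("\\btype\\s*(1|one|i)\\b|\\bjuvenile\\s+diabetes\\b|\\biddm\\b",
              text, perl = TRUE)
  t2 <- grepl("\\btype\\s*(2|two|ii)\\b|\\bgrade\\s*2\\b|\\bniddm\\b|\\bmature\\s+onset\\b",
              text, perl = TRUE)
  out <- rep("none", length(text))
  out[t2] <- "type2"
  out[t1] <- "type1"  # when both are written, the type 1 statement wins
  out
}

#' Classify the type of diabetes from questionnaire evidence
#'
#' Applies the typing rules, in order, to participants already assigned to
#' the diabetes group: (1) a free-text declaration of type 1 assigns
#' `type1`; (2) a declaration of type 2 assigns `type2`; (3) insulin use
#' with diagnosis before age 31 (age at diagnosis of 30 or less) or with
#' no age of diagnosis given assigns `type1`; (4) women diagnosed before
#' the age at their last delivery who report no current diabetes
#' medication are assigned `gestational_other`; (5) everyone else is
#' `type2`.
#'
#' @param evidence data frame with columns `free_text_declared_type`
#'   (`"type1"`, `"type2"`, `"none"`), `uses_insulin`, `uses_oha`
#'   (logical), `age_at_diagnosis` (integer, `NA` when missing), `sex`,
#'   `age_at_last_delivery` (integer, `NA` when missing).
#' @return character vector with values `"type1"`, `"type2"` or
#'   `"gestational_other"`, with attribute `rule` recording which rule
#'   fired for each participant (`declared_type1`, `declared_type2`,
#'   `insulin_young`, `insulin_no_age`, `gestational`, `residual_type2`).
#' @export
classify_type <- function(evidence) {
  required <- c("free_text_declared_type", "uses_insulin", "uses_oha",
                "age_at_diagnosis", "sex", "age_at_last_delivery")
  missing_cols <- setdiff(required, names(evidence))
  if (length(missing_cols) > 0) {
    stop("evidence is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(evidence)
  type <- rep(NA_character_, n)
  rule <- rep(NA_character_, n)

  d1 <- evidence$free_text_declared_type == "type1"
  d2 <- is.na(type) & !d1 & evidence$free_text_declared_type == "type2"
  type[d1] <- "type1"; rule[d1] <- "declared_type1"
  type[d2] <- "type2"; rule[d2] <- "declared_type2"

  open <- is.na(type)
  ins_young <- open & evidence$uses_insulin &
    !is.na(evidence$age_at_diagnosis) & evidence$age_at_diagnosis <= 30
  type[ins_young] <- "type1"; rule[ins_young] <- "insulin_young"
  open <- is.na(type)
  ins_noage <- open & evidence$uses_insulin & is.na(evidence$age_at_diagnosis)
  type[ins_noage] <- "type1"; rule[ins_noage] <- "insulin_no_age"

  open <- is.na(type)
  gest <- open & evidence$sex == "female" &
    !is.na(evidence$age_at_diagnosis) &
    !is.na(evidence$age_at_last_delivery) &
    evidence$age_at_diagnosis < evidence$age_at_last_delivery &
    !(evidence$uses_insulin | evidence$uses_oha)
  type[gest] <- "gestational_other"; rule[gest] <- "gestational"

  open <- is.na(type)
  type[open] <- "type2"; rule[open] <- "residual_type2"

  attr(type, "rule") <- rule
  type
}

#' Classify diabetes type across a cohort
#'
#' Builds the typing evidence for every participant in the diabetes group
#' (declared type from the illness free text, insulin/OHA self-report from
#' the status algorithm, age at diagnosis, sex, age at last delivery) and
#' applies [classify_type()]. Participants not in the diabetes group keep
#' `diabetes_type = "not_applicable"`.
#'
#' @param assignments assignment data frame from [phenotype_cohort()].
#' @param questionnaire validated questionnaire data frame.
#' @return `assignments` with `diabetes_type` filled in, plus attributes
#'   `type_counts` (per-type totals), `rule_counts` (participants routed by
#'   each typing rule) and `conflicts` (count of declared-type-2
#'   participants whose medication/age evidence pointed to type 1).
#' @export
type_cohort <- function(assignments, questionnaire) {
  if (!all(assignments$participant_id %in% questionnaire$participant_id)) {
    stop("assignments contain participants absent from the questionnaire")
  }
  idx <- match(assignments$participant_id, questionnaire$participant_id)
  q <- questionnaire[idx, , drop = FALSE]
  dg <- assignments$status == "diabetes"

  if (any(assignments$diabetes_type[!dg] != "not_applicable", na.rm = TRUE)) {
    stop("non-diabetes participants must carry diabetes_type 'not_applicable'")
  }

  evidence <- data.frame(
    free_text_declared_type = detect_declared_type(q$other_illness_text[dg]),
    uses_insulin = assignments$self_reported_insulin[dg],
    uses_oha = assignments$self_reported_oha[dg],
    age_at_diagnosis = q$age_at_diagnosis[dg],
    sex = q$sex[dg],
    age_at_last_delivery = q$age_at_last_delivery[dg],
    stringsAsFactors = FALSE
  )
  type <- classify_type(evidence)
  rule <- attr(type, "rule")

  out <- assignments
  out$diabetes_type[dg] <- as.character(type)

  conflicts <- sum(evidence$free_text_declared_type == "type2" &
                     evidence$uses_insulin &
                     (is.na(evidence$age_at_diagnosis) |
                        evidence$age_at_diagnosis <= 30))
  if (conflicts > 0) {
    message(sprintf(
      "type_cohort: %d declared-type-2 participant(s) with insulin/age evidence for type 1; declaration kept",
      conflicts))
  }
  attr(out, "type_counts") <- table(factor(out$diabetes_type[dg],
                                           levels = TYPE_LEVELS[1:3]))
  attr(out, "rule_counts") <- table(rule)
  attr(out, "conflicts") <- conflicts
  log_stage("type_cohort", nrow(assignments), c(non_diabetes = sum(!dg)),
            sum(dg))
  out
}
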