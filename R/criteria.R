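#' Validation windows and thresholds
#'
#' Collects the date windows and thresholds that define the three
#' administrative criterion standards. All date windows are closed
#' intervals on calendar dates.
#'
#' @param apdc_start,apdc_end hospital-admission extraction window
#'   (default 2000-07-01 to 2009-12-31).
#' @param hba1c_years two calendar years bounding the HbA1c claim counting
#'   window (default 2005–2009; claims are extracted from 2004 but counted
#'   from 2005).
#' @param pbs_lookback_days dispensing look-back before recruitment in
#'   days (default 365).
#' @param hba1c_item service item number identifying an HbA1c test claim
#'   (default 66551).
#' @param hba1c_min_claims minimum number of HbA1c claims for a positive
#'   criterion (1 or 2; default 1).
#' @param diabetes_code_prefixes ICD-10-AM prefixes counted as a diabetes
#'   diagnosis.
#' @param gestational_code_prefixes ICD-10-AM prefixes treated as
#'   gestational; participants whose only diabetes codes fall in this set
#'   are excluded from the hospital-data comparison.
#' @return an object of class `window_config`.
#' @export
window_config <- function(apdc_start = "2000-07-01",
                          apdc_end = "2009-12-31",
                          hba1c_years = c(2005L, 2009L),
                          pbs_lookback_days = 365L,
                          hba1c_item = 66551L,
                          hba1c_min_claims = 1L,
                          diabetes_code_prefixes =
                            c("E10", "E11", "E13", "E14",
                              "O24.0", "O24.1", "O24.2", "O24.3"),
                          gestational_code_prefixes = c("O24")) {
  cfg <- list(apdc_start = as.Date(apdc_start),
              apdc_end = as.Date(apdc_end),
              hba1c_years = as.integer(hba1c_years),
              pbs_lookback_days = as.integer(pbs_lookback_days),
              hba1c_item = as.integer(hba1c_item),
              hba1c_min_claims = as.integer(hba1c_min_claims),
              diabetes_code_prefixes = diabetes_code_prefixes,
              gestational_code_prefixes = gestational_code_prefixes)
  if (cfg$apdc_end < cfg$apdc_start) stop("empty admission window")
  if (length(cfg$hba1c_years) != 2 || cfg$hba1c_years[2] < cfg$hba1c_years[1]) {
    stop("hba1c_years must be an ordered pair of calendar years")
  }
  if (cfg$hba1c_min_claims < 1) stop("hba1c_min_claims must be >= 1")
  if (cfg$pbs_lookback_days < 1) stop("pbs_lookback_days must be >= 1")
  class(cfg) <- "window_config"
  cfg
}

# prefix match on normalised ICD-10-AM codes (upper case, dots retained):
# "E11" matches "E11" and "E11.9"; "O24.0" matches "O24.0" and "O24.01"
code_matches <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

# one row per diagnosis code: participant_id + code
explode_codes <- function(admissions) {
  code_list <- strsplit(admissions$diagnosis_codes, ";", fixed = TRUE)
  data.frame(participant_id = rep(admissions$participant_id,
                                  lengths(code_list)),
             code = unlist(code_list, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# self-reported diagnosis year: year of birth + age at diagnosis, defined
# only for diabetes-group participants who gave an age (year resolution,
# +-1 year uncertainty inherent in combining two year-valued fields)
self_report_diag_year <- function(questionnaire, assignments) {
  idx <- match(questionnaire$participant_id, assignments$participant_id)
  status <- assignments$status[idx]
  ifelse(status == "diabetes" & !is.na(questionnaire$age_at_diagnosis),
         questionnaire$year_of_birth + questionnaire$age_at_diagnosis,
         NA_integer_)
}

criterion_frame <- function(ids, source) {
  data.frame(participant_id = ids, source = source, included = FALSE,
             exclusion_reason = NA_character_, criterion_positive = NA,
             stringsAsFactors = FALSE)
}

#' Derive the hospital-record diabetes type per participant
#'
#' Pools the ICD-10-AM diagnosis codes across a participant's admissions
#' and assigns a single hospital-record type with precedence
#' E10 (type 1) over E11 (type 2) over E13 / O24.0–O24.3
#' (gestational/other) over E14 (unspecified); participants with no
#' diabetes code at all are labelled `no_diabetes_code`. Multi-code
#' conflicts (both E10 and E11 present) are resolved by that precedence
#' and counted in the `conflicts` attribute.
#'
#' @param admissions admission data frame (already restricted to the
#'   extraction window).
#' @param ids participant identifiers to type; defaults to the
#'   participants present in `admissions`.
#' @return a data frame with columns `participant_id` and `apdc_type`,
#'   with attribute `conflicts`.
#' @export
apdc_type <- function(admissions, ids = unique(admissions$participant_id)) {
  cc <- explode_codes(admissions)
  e10 <- ids %in% cc$participant_id[code_matches(cc$code, "E10")]
  e11 <- ids %in% cc$participant_id[code_matches(cc$code, "E11")]
  gest <- ids %in% cc$participant_id[
    code_matches(cc$code, c("E13", "O24.0", "O24.1", "O24.2", "O24.3"))]
  e14 <- ids %in% cc$participant_id[code_matches(cc$code, "E14")]
  type <- rep("no_diabetes_code", length(ids))
  type[e14] <- "unspecified"
  type[gest] <- "gestational_other"
  type[e11] <- "type2"
  type[e10] <- "type1"
  out <- data.frame(participant_id = ids, apdc_type = type,
                    stringsAsFactors = FALSE)
  attr(out, "conflicts") <- sum(e10 & e11)
  out
}

#' Hospital-admission (APDC) criterion standard
#'
#' Builds the analysis subset and the binary criterion indicator for the
#' hospital-data comparison. Participants are excluded, in order of
#' precedence, when they could not be linked to the hospital collection,
#' had no admission within the extraction window, self-reported a
#' diagnosis year later than the year of their last admission, or carry
#' gestational diabetes codes only. For included participants the
#' criterion is positive when any admission carries a diabetes code
#' (prefixes E10, E11, E13, E14, O24.0–O24.3) in any diagnostic position.
#'
#' @param cohort a `dm_cohort`.
#' @param assignments assignments from [phenotype_cohort()].
#' @param config a [window_config()].
#' @return a criterion data frame (one row per participant) with columns
#'   `participant_id`, `source`, `included`, `exclusion_reason`,
#'   `criterion_positive` and `apdc_type`.
#' @export
apdc_criterion <- function(cohort, assignments, config = window_config()) {
  q <- cohort$questionnaire
  adm <- cohort$admissions
  outside <- adm$admission_date < config$apdc_start |
    adm$admission_date > config$apdc_end
  if (any(outside)) {
    warning(sprintf("ignoring %d admission(s) outside the extraction window",
                    sum(outside)))
    adm <- adm[!outside, , drop = FALSE]
  }

  res <- criterion_frame(q$participant_id, "apdc")
  link <- cohort$linkage$linked_apdc[match(q$participant_id,
                                           cohort$linkage$participant_id)]

  has_adm <- q$participant_id %in% adm$participant_id
  last_year <- tapply(as.integer(format(adm$admission_date, "%Y")),
                      adm$participant_id, max)
  last_year <- as.integer(last_year[match(q$participant_id, names(last_year))])
  diag_year <- self_report_diag_year(q, assignments)

  cc <- explode_codes(adm)
  is_dm_code <- code_matches(cc$code, config$diabetes_code_prefixes)
  is_gest_code <- code_matches(cc$code, config$gestational_code_prefixes)
  any_dm <- q$participant_id %in% cc$participant_id[is_dm_code]
  any_nongest_dm <- q$participant_id %in%
    cc$participant_id[is_dm_code & !is_gest_code]
  gest_only <- any_dm & !any_nongest_dm

  reason <- rep("none", nrow(q))
  reason[gest_only] <- "gestational_only"
  reason[!is.na(diag_year) & !is.na(last_year) & diag_year > last_year] <-
    "diagnosed_after_last_admission"
  reason[!has_adm] <- "no_admission"
  reason[!link] <- "not_linked"

  res$included <- reason == "none"
  res$exclusion_reason <- reason
  res$criterion_positive <- ifelse(res$included, any_dm, NA)

  types <- apdc_type(adm, q$participant_id)
  res$apdc_type <- ifelse(res$included, types$apdc_type, "not_applicable")

  excl <- table(reason[reason != "none"])
  log_stage("apdc_criterion", nrow(q),
            stats::setNames(as.integer(excl), names(excl)),
            sum(res$included))
  res
}

#' HbA1c-claim (MBS) criterion standard
#'
#' Participants are excluded when not linked to the service-claims data or
#' when their self-reported diagnosis year falls after the end of the
#' claim counting window. For included participants the criterion is
#' positive when the number of HbA1c test claims (the configured item
#' number) with a service year inside the counting window reaches
#' `hba1c_min_claims`.
#'
#' @inheritParams apdc_criterion
#' @return a criterion data frame, as for [apdc_criterion()] but without
#'   the `apdc_type` column.
#' @export
mbs_criterion <- function(cohort, assignments, config = window_config()) {
  q <- cohort$questionnaire
  res <- criterion_frame(q$participant_id, "mbs")
  link <- cohort$linkage$linked_medicare[match(q$participant_id,
                                               cohort$linkage$participant_id)]
  diag_year <- self_report_diag_year(q, assignments)

  claims <- cohort$mbs
  claims <- claims[claims$item_number == config$hba1c_item, , drop = FALSE]
  yr <- as.integer(format(claims$service_date, "%Y"))
  in_window <- yr >= config$hba1c_years[1] & yr <= config$hba1c_years[2]
  counts <- table(claims$participant_id[in_window])
  n_claims <- as.integer(counts[match(q$participant_id, names(counts))])
  n_claims[is.na(n_claims)] <- 0L

  reason <- rep("none", nrow(q))
  reason[!is.na(diag_year) & diag_year > config$hba1c_years[2]] <-
    "diagnosis_after_window"
  reason[!link] <- "not_linked"

  res$included <- reason == "none"
  res$exclusion_reason <- reason
  res$criterion_positive <- ifelse(res$included,
                                   n_claims >= config$hba1c_min_claims, NA)
  excl <- table(reason[reason != "none"])
  log_stage("mbs_criterion", nrow(q),
            stats::setNames(as.integer(excl), names(excl)),
            sum(res$included))
  res
}

#' Dispensing-claim (PBS) criterion standard
#'
#' Participants are excluded when not linked to the claims data, when they
#' have no dispensing claim of any kind during the look-back window before
#' recruitment (no observable dispensing history), or when they hold a
#' veterans'-affairs treatment card (whose medications bypass the claims
#' collection). For included participants the criterion is positive when
#' at least one claim in the look-back window is for insulin or an oral
#' hypoglycaemic agent.
#'
#' @inheritParams apdc_criterion
#' @return a criterion data frame, as for [mbs_criterion()].
#' @export
pbs_criterion <- function(cohort, assignments, config = window_config()) {
  q <- cohort$questionnaire
  res <- criterion_frame(q$participant_id, "pbs")
  link <- cohort$linkage$linked_medicare[match(q$participant_id,
                                               cohort$linkage$participant_id)]

  claims <- cohort$pbs
  idx <- match(claims$participant_id, q$participant_id)
  recruit <- q$recruitment_date[idx]
  in_window <- !is.na(recruit) &
    claims$supply_date >= recruit - config$pbs_lookback_days &
    claims$supply_date < recruit
  w <- claims[in_window, , drop = FALSE]

  has_claim <- q$participant_id %in% w$participant_id
  dm_claim_ids <- unique(w$participant_id[w$medication_class != "non_diabetes"])
  dm_claim <- q$participant_id %in% dm_claim_ids

  reason <- rep("none", nrow(q))
  reason[q$dva_card] <- "dva_card"
  reason[!has_claim] <- "no_pbs_claims"
  reason[!link] <- "not_linked"

  res$included <- reason == "none"
  res$exclusion_reason <- reason
  res$criterion_positive <- ifelse(res$included, dm_claim, NA)
  excl <- table(reason[reason != "none"])
  log_stage("pbs_criterion", nrow(q),
            stats::setNames(as.integer(excl), names(excl)),
            sum(res$included))
  res
}
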