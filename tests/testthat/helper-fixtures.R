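# Fixture builders shared across the suite. Everything is constructed in
# code; nothing is read from disk except the packaged lexicons and
# reference tables.

# one questionnaire row with sensible defaults, overridable per field
q_row <- function(participant_id = "P1",
                  recruitment_date = as.Date("2008-06-15"),
                  sex = "male",
                  year_of_birth = 1950L,
                  diabetes_tickbox = FALSE,
                  age_at_diagnosis = NA_integer_,
                  other_illness_text = "",
                  metformin_tickbox = FALSE,
                  medication_text = "",
                  dva_card = FALSE,
                  age_at_last_delivery = NA_integer_) {
  data.frame(participant_id = participant_id,
             recruitment_date = recruitment_date, sex = sex,
             year_of_birth = year_of_birth,
             diabetes_tickbox = diabetes_tickbox,
             age_at_diagnosis = age_at_diagnosis,
             other_illness_text = other_illness_text,
             metformin_tickbox = metformin_tickbox,
             medication_text = medication_text, dva_card = dva_card,
             age_at_last_delivery = age_at_last_delivery,
             stringsAsFactors = FALSE)
}

adm_row <- function(participant_id, admission_date, diagnosis_codes) {
  data.frame(participant_id = participant_id,
             admission_date = as.Date(admission_date),
             diagnosis_codes = diagnosis_codes, stringsAsFactors = FALSE)
}

mbs_row <- function(participant_id, service_date, item_number = 66551L) {
  data.frame(participant_id = participant_id,
             service_date = as.Date(service_date),
             item_number = item_number, stringsAsFactors = FALSE)
}

pbs_row <- function(participant_id, supply_date, medication_class) {
  data.frame(participant_id = participant_id,
             supply_date = as.Date(supply_date),
             medication_class = medication_class, stringsAsFactors = FALSE)
}

empty_adm <- function() adm_row(character(0), as.Date(character(0)),
                                character(0))
empty_mbs <- function() mbs_row(character(0), as.Date(character(0)),
                                integer(0))
empty_pbs <- function() pbs_row(character(0), as.Date(character(0)),
                                character(0))

# assemble a dm_cohort from parts; linkage defaults to fully linked
make_cohort <- function(questionnaire, admissions = empty_adm(),
                        mbs = empty_mbs(), pbs = empty_pbs(),
                        linkage = NULL) {
  if (is.null(linkage)) {
    linkage <- data.frame(participant_id = questionnaire$participant_id,
                          linked_apdc = TRUE, linked_medicare = TRUE,
                          stringsAsFactors = FALSE)
  }
  structure(list(questionnaire = questionnaire, admissions = admissions,
                 mbs = mbs, pbs = pbs, linkage = linkage),
            class = "dm_cohort")
}

# assignment row for agreement tests that bypass the phenotyping stage
assign_row <- function(participant_id, status,
                       diabetes_type = if (status == "diabetes") "type2"
                                       else "not_applicable") {
  data.frame(participant_id = participant_id, status = status,
             evidence = switch(status, diabetes = "tickbox",
                               uncertain = "oha_text", "none"),
             self_reported_insulin = FALSE, self_reported_oha = FALSE,
             diabetes_type = diabetes_type, stringsAsFactors = FALSE)
}

# reference 2x2 tables packaged with the module (published
# cross-tabulations the statistics are checked against)
reference_tables <- function() {
  utils::read.csv(system.file("extdata", "reference_tables.csv",
                              package = "diablink"), stringsAsFactors = FALSE)
}

# independent textbook implementation of the agreement statistics,
# computed from an expanded individual-level cross-classification rather
# than from the closed-form marginal expressions
oracle_stats <- function(tp, fp, fn, tn) {
  report <- rep(c(1, 1, 0, 0), times = c(tp, fp, fn, tn))
  crit <- rep(c(1, 0, 1, 0), times = c(tp, fp, fn, tn))
  n <- length(report)
  p_o <- mean(report == crit)
  p_e <- mean(report) * mean(crit) + mean(1 - report) * mean(1 - crit)
  list(sensitivity = mean(report[crit == 1]),
       specificity = 1 - mean(report[crit == 0]),
       ppv = mean(crit[report == 1]),
       npv = 1 - mean(crit[report == 0]),
       kappa = (p_o - p_e) / (1 - p_e))
}
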