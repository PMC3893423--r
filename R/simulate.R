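# Stream identifiers for the counter-based generator. Each questionnaire
# field / event family owns one stream, so the draws for participant i are
# a pure function of (seed, stream, i) and never shift when the cohort is
# enlarged.
STREAMS <- list(
  sex = 1, age = 2, recruit = 3, true_status = 4, true_type = 5,
  tick = 6, free_text = 7, free_text_term = 8, declared_type = 9,
  adm_date_extra = 10,
  agediag_missing = 11, agediag = 12, insulin = 13, insulin_term = 14,
  oha = 15, oha_mode = 16, oha_term = 17, dva = 18, link_apdc = 19,
  link_medicare = 20, admitted = 21, adm_extra = 22, adm_date = 23,
  adm_bg_code = 24, dm_code = 25, dm_code_adm = 26, dm_code_variant = 27,
  hba1c_in = 28, hba1c_in_date = 29, hba1c_out = 30, hba1c_out_date = 31,
  pbs_dm = 32, pbs_dm_extra = 33, pbs_dm_date = 34, pbs_dm_class = 35,
  pbs_bg = 36, pbs_bg_date = 37, decoy = 38, decoy_term = 39,
  delivery_has = 40, delivery_age = 41, uncertain_text = 42,
  uncertain_term = 43, free_text_pick = 44
)

ADM_SLOT_CAP <- 8L      # max admissions per participant
CLAIM_SLOT_CAP <- 64L   # max claims per participant per claim family

INSULIN_TERMS <- c("insulin", "lantus", "novorapid", "humalog", "protaphane")
OHA_TERMS <- c("gliclazide", "diamicron", "metformin", "avandia", "januvia")
POSITIVE_TERMS <- c("diabetes", "sugar diabetes", "diabetes mellitus")
UNCERTAIN_TERMS <- c("borderline diabetes", "pre-diabetes",
                     "diabetes insipidus", "impaired glucose tolerance")
DECOY_TERMS <- c("arthritis", "asthma", "hypertension", "depression",
                 "heart disease")
BG_ICD_CODES <- c("I10", "I21.0", "J18.9", "K80.2", "M54.5", "N39.0",
                  "E78.0", "S72.0")

#' Parameters of the synthetic linked cohort
#'
#' Defines the probability model of the synthetic cohort generator. The
#' defaults describe a population cohort of older adults with a true
#' diabetes prevalence near 9%, near-complete record linkage, roughly
#' three-quarters of participants admitted to hospital over a decade, and
#' per-source misclassification consistent with the margins observed in
#' large Australian linkage validation work; the methods vignette records
#' how each default was chosen.
#'
#' @param n cohort size.
#' @param prevalence probability of true prevalent diabetes.
#' @param type1_fraction fraction of true diabetics with type 1 disease.
#' @param tick_sens,tick_spec probability that a true diabetic ticks the
#'   diagnosis box / that a non-diabetic leaves it unticked.
#' @param free_text_rate probability that a true diabetic who did not
#'   tick writes a positive diabetes phrase in the illness free text.
#' @param uncertain_text_rate probability that a non-ticking non-diabetic
#'   writes an uncertain phrase (pre-diabetes and the like).
#' @param insulin_given_type1,insulin_given_type2 probability a diabetic
#'   of each type self-reports an insulin product.
#' @param oha_given_diabetes probability a diabetic self-reports an oral
#'   hypoglycaemic agent (tick box or text).
#' @param admit_prob probability of at least one hospital admission in
#'   the extraction window.
#' @param code_sens probability an admitted diabetic has a diabetes
#'   ICD-10-AM code recorded; `1 - code_spec` is the corresponding
#'   miscoding probability for admitted non-diabetics.
#' @param code_spec see `code_sens`.
#' @param hba1c_rate_diabetes,hba1c_rate_other expected annual HbA1c claim
#'   counts by true status (Poisson).
#' @param pbs_claim_sens,pbs_claim_fpr probability of at least one
#'   diabetes-medication dispensing claim in the look-back year, by true
#'   status.
#' @param pbs_background_rate expected number of unrelated dispensing
#'   claims in the look-back year (Poisson; gives non-diabetics an
#'   observable dispensing history).
#' @param dva_prob probability of holding a veterans'-affairs card.
#' @param link_prob probability of successful linkage (applied
#'   independently to the hospital and the claims collections).
#' @param decoy_text_rate probability that a participant with no
#'   diabetes-related text writes an unrelated illness phrase.
#' @param seed integer seed of the counter-based random stream.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n = 100000L,
                             prevalence = 0.0905,
                             type1_fraction = 0.037,
                             tick_sens = 0.88,
                             tick_spec = 0.9985,
                             free_text_rate = 0.04,
                             uncertain_text_rate = 0.0006,
                             insulin_given_type1 = 0.95,
                             insulin_given_type2 = 0.10,
                             oha_given_diabetes = 0.58,
                             admit_prob = 0.72,
                             code_sens = 0.84,
                             code_spec = 0.978,
                             hba1c_rate_diabetes = 0.45,
                             hba1c_rate_other = 0.01,
                             pbs_claim_sens = 0.714,
                             pbs_claim_fpr = 0.0035,
                             pbs_background_rate = 3,
                             dva_prob = 0.024,
                             link_prob = 0.995,
                             decoy_text_rate = 0.05,
                             seed = 1L) {
  p <- list(n = as.integer(n), prevalence = prevalence,
            type1_fraction = type1_fraction, tick_sens = tick_sens,
            tick_spec = tick_spec, free_text_rate = free_text_rate,
            uncertain_text_rate = uncertain_text_rate,
            insulin_given_type1 = insulin_given_type1,
            insulin_given_type2 = insulin_given_type2,
            oha_given_diabetes = oha_given_diabetes,
            admit_prob = admit_prob, code_sens = code_sens,
            code_spec = code_spec,
            hba1c_rate_diabetes = hba1c_rate_diabetes,
            hba1c_rate_other = hba1c_rate_other,
            pbs_claim_sens = pbs_claim_sens, pbs_claim_fpr = pbs_claim_fpr,
            pbs_background_rate = pbs_background_rate,
            dva_prob = dva_prob, link_prob = link_prob,
            decoy_text_rate = decoy_text_rate, seed = as.integer(seed))
  if (is.na(p$n) || p$n < 1) stop("invalid generator parameter: n")
  probs <- c("prevalence", "type1_fraction", "tick_sens", "tick_spec",
             "free_text_rate", "uncertain_text_rate", "insulin_given_type1",
             "insulin_given_type2", "oha_given_diabetes", "admit_prob",
             "code_sens", "code_spec", "pbs_claim_sens", "pbs_claim_fpr",
             "dva_prob", "link_prob", "decoy_text_rate")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      stop("invalid generator parameter: ", nm)
    }
  }
  for (nm in c("hba1c_rate_diabetes", "hba1c_rate_other",
               "pbs_background_rate")) {
    if (!is.numeric(p[[nm]]) || is.na(p[[nm]]) || p[[nm]] < 0) {
      stop("invalid generator parameter: ", nm)
    }
  }
  if (is.na(p$seed)) stop("invalid generator parameter: seed")
  class(p) <- "generator_params"
  p
}

# per-slot event dates/claims built by looping over slots (vectorised over
# participants); returns data.frame(participant_id, slot, date)
slot_dates <- function(seed, stream, ids, counts, cap, from, to) {
  counts <- pmin(counts, cap)
  out <- vector("list", max(counts, 0))
  i_all <- seq_along(ids)
  for (j in seq_len(max(counts, 0))) {
    sel <- counts >= j
    if (!any(sel)) break
    i <- i_all[sel]
    out[[j]] <- data.frame(
      participant_id = ids[sel],
      slot = j,
      date = r_date(seed, stream, slot_index(i, j, cap),
                    if (length(from) > 1) from[sel] else from,
                    if (length(to) > 1) to[sel] else to),
      stringsAsFactors = FALSE)
  }
  if (all(vapply(out, is.null, logical(1)))) {
    data.frame(participant_id = character(0), slot = integer(0),
               date = as.Date(character(0)), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }
}

#' Generate a synthetic linked cohort with known ground truth
#'
#' Simulates a baseline questionnaire, hospital admissions with
#' ICD-10-AM code lists, HbA1c service claims, pharmacy dispensing claims
#' and linkage flags under the probability model of
#' [generator_params()], together with a truth table recording each
#' participant's true diabetes status and type. Every stochastic quantity
#' is drawn from a counter-based stream keyed by (seed, field,
#' participant), so the same parameters reproduce the same cohort
#' byte-for-byte and enlarging `n` leaves earlier participants unchanged.
#'
#' Admitted participants always receive one admission on or after their
#' recruitment date (their admission history covers the prevalent
#' diagnosis), plus a Poisson number of further admissions across the
#' extraction window.
#'
#' @param params a [generator_params()] object.
#' @param config a [window_config()]; the generator draws event dates
#'   inside its windows.
#' @return a `dm_cohort` list (questionnaire, admissions, mbs, pbs,
#'   linkage, truth) with attribute `params`.
#' @export
simulate_cohort <- function(params = generator_params(),
                            config = window_config()) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n
  seed <- params$seed
  i <- seq_len(n)
  ids <- sprintf("P%07d", i)
  S <- STREAMS

  sex <- ifelse(r_bern(seed, S$sex, i, 0.5), "female", "male")
  age <- r_int(seed, S$age, i, 45L, 89L)
  recruit <- r_date(seed, S$recruit, i, "2006-01-01", "2009-06-30")
  yob <- as.integer(format(recruit, "%Y")) - age

  diabetic <- r_bern(seed, S$true_status, i, params$prevalence)
  type1 <- diabetic & r_bern(seed, S$true_type, i, params$type1_fraction)
  true_type <- ifelse(!diabetic, NA_character_,
                      ifelse(type1, "type1", "type2"))

  # -- questionnaire ---------------------------------------------------
  p_tick <- ifelse(diabetic, params$tick_sens, 1 - params$tick_spec)
  tick <- r_bern(seed, S$tick, i, p_tick)

  writes_pos <- diabetic & !tick & r_bern(seed, S$free_text, i,
                                          params$free_text_rate)
  type_specific <- r_bern(seed, S$free_text_term, i, 0.25)
  pos_term <- ifelse(type_specific,
                     ifelse(type1, "type 1 diabetes", "type 2 diabetes"),
                     r_pick(seed, S$free_text_pick, i, POSITIVE_TERMS))

  # some tick-box diabetics also state their type in the illness text
  declares <- diabetic & tick & r_bern(seed, S$declared_type, i, 0.07)
  declared_term <- ifelse(type1, "diabetes type 1", "diabetes type 2")

  writes_unc <- !diabetic & !tick &
    r_bern(seed, S$uncertain_text, i, params$uncertain_text_rate)
  unc_term <- r_pick(seed, S$uncertain_term, i, UNCERTAIN_TERMS)

  illness <- rep("", n)
  illness[writes_pos] <- pos_term[writes_pos]
  illness[declares] <- declared_term[declares]
  illness[writes_unc] <- unc_term[writes_unc]
  decoy <- !nzchar(illness) & r_bern(seed, S$decoy, i, params$decoy_text_rate)
  illness[decoy] <- r_pick(seed, S$decoy_term, i, DECOY_TERMS)[decoy]

  p_ins <- ifelse(type1, params$insulin_given_type1,
                  params$insulin_given_type2)
  ins_report <- diabetic & r_bern(seed, S$insulin, i, p_ins)
  ins_term <- r_pick(seed, S$insulin_term, i, INSULIN_TERMS)

  oha_report <- diabetic & r_bern(seed, S$oha, i, params$oha_given_diabetes)
  oha_by_tick <- oha_report & r_bern(seed, S$oha_mode, i, 0.85)
  oha_by_text <- oha_report & !oha_by_tick
  oha_term <- r_pick(seed, S$oha_term, i, OHA_TERMS)

  med_text <- rep("", n)
  med_text[ins_report] <- ins_term[ins_report]
  both <- ins_report & oha_by_text
  med_text[both] <- paste(ins_term[both], oha_term[both], sep = "; ")
  only_oha <- !ins_report & oha_by_text
  med_text[only_oha] <- oha_term[only_oha]

  # age at diagnosis is asked of tick-box respondents
  agediag <- rep(NA_integer_, n)
  asked <- tick & !r_bern(seed, S$agediag_missing, i, 0.05)
  lo <- ifelse(diabetic & type1, 5L,
               ifelse(diabetic, pmin(35L, age), pmin(30L, age)))
  hi <- ifelse(diabetic & type1, pmin(30L, age), age)
  agediag[asked] <- r_int(seed, S$agediag, i, lo, hi)[asked]

  delivery <- rep(NA_integer_, n)
  has_del <- sex == "female" & r_bern(seed, S$delivery_has, i, 0.8)
  delivery[has_del] <- r_int(seed, S$delivery_age, i, 18L, 42L)[has_del]

  dva <- r_bern(seed, S$dva, i, params$dva_prob)

  questionnaire <- data.frame(
    participant_id = ids,
    recruitment_date = recruit,
    sex = sex,
    year_of_birth = yob,
    diabetes_tickbox = tick,
    age_at_diagnosis = agediag,
    other_illness_text = illness,
    metformin_tickbox = oha_by_tick,
    medication_text = med_text,
    dva_card = dva,
    age_at_last_delivery = delivery,
    stringsAsFactors = FALSE
  )

  # -- hospital admissions ----------------------------------------------
  admitted <- r_bern(seed, S$admitted, i, params$admit_prob)
  n_adm <- ifelse(admitted,
                  1L + pmin(r_pois(seed, S$adm_extra, i, 1.5),
                            ADM_SLOT_CAP - 1L), 0L)
  # slot 1: on or after recruitment (history covers the prevalent case);
  # remaining slots: anywhere in the extraction window
  first <- slot_dates(seed, S$adm_date, ids, as.integer(admitted), 1L,
                      recruit, config$apdc_end)
  extra <- slot_dates(seed, S$adm_date_extra, ids, pmax(n_adm - 1L, 0L),
                      ADM_SLOT_CAP - 1L,
                      config$apdc_start, config$apdc_end)
  extra$slot <- extra$slot + 1L
  adm <- rbind(first, extra)

  # two background codes per admission
  row_i <- match(adm$participant_id, ids)
  bg1 <- r_pick(seed, S$adm_bg_code,
                slot_index(row_i, 2L * adm$slot - 1L, 2L * ADM_SLOT_CAP),
                BG_ICD_CODES)
  bg2 <- r_pick(seed, S$adm_bg_code,
                slot_index(row_i, 2L * adm$slot, 2L * ADM_SLOT_CAP),
                BG_ICD_CODES)
  adm$codes <- paste(bg1, bg2, sep = ";")

  # at most one diabetes coding decision per participant, attached to a
  # randomly chosen admission
  p_code <- ifelse(diabetic, params$code_sens, 1 - params$code_spec)
  coded <- admitted & r_bern(seed, S$dm_code, i, p_code)
  code_slot <- 1L + floor(r_unif(seed, S$dm_code_adm, i) * n_adm)
  uvar <- r_unif(seed, S$dm_code_variant, i)
  dm_code <- ifelse(type1,
                    ifelse(uvar < 0.7, "E10.9", "E10.1"),
             ifelse(diabetic,
                    ifelse(uvar < 0.80, "E11.9",
                    ifelse(uvar < 0.90, "E11.2",
                    ifelse(uvar < 0.97, "E14", "E13.9"))),
                    ifelse(uvar < 0.85, "E11.9", "E14")))
  tag <- coded[row_i] & adm$slot == code_slot[row_i]
  adm$codes[tag] <- paste(adm$codes[tag], dm_code[row_i][tag], sep = ";")

  admissions <- data.frame(participant_id = adm$participant_id,
                           admission_date = adm$date,
                           diagnosis_codes = adm$codes,
                           stringsAsFactors = FALSE)
  admissions <- admissions[order(admissions$participant_id,
                                 admissions$admission_date,
                                 admissions$diagnosis_codes), , drop = FALSE]
  rownames(admissions) <- NULL

  # -- HbA1c service claims ---------------------------------------------
  span <- config$hba1c_years[2] - config$hba1c_years[1] + 1
  rate <- ifelse(diabetic, params$hba1c_rate_diabetes,
                 params$hba1c_rate_other)
  n_in <- r_pois(seed, S$hba1c_in, i, span * rate)
  n_out <- r_pois(seed, S$hba1c_out, i, 1 * rate)  # extraction-only year
  claims_in <- slot_dates(seed, S$hba1c_in_date, ids, n_in, CLAIM_SLOT_CAP,
                          as.Date(sprintf("%d-01-01", config$hba1c_years[1])),
                          as.Date(sprintf("%d-12-31", config$hba1c_years[2])))
  claims_out <- slot_dates(seed, S$hba1c_out_date, ids, n_out, CLAIM_SLOT_CAP,
                           as.Date(sprintf("%d-01-01",
                                           config$hba1c_years[1] - 1)),
                           as.Date(sprintf("%d-12-31",
                                           config$hba1c_years[1] - 1)))
  mbs <- rbind(claims_in, claims_out)
  mbs <- data.frame(participant_id = mbs$participant_id,
                    service_date = mbs$date,
                    item_number = config$hba1c_item,
                    stringsAsFactors = FALSE)
  mbs <- mbs[order(mbs$participant_id, mbs$service_date), , drop = FALSE]
  rownames(mbs) <- NULL

  # -- pharmacy dispensing claims ---------------------------------------
  p_dm_claim <- ifelse(diabetic, params$pbs_claim_sens, params$pbs_claim_fpr)
  dm_claims <- r_bern(seed, S$pbs_dm, i, p_dm_claim)
  n_dm <- ifelse(dm_claims,
                 1L + pmin(r_pois(seed, S$pbs_dm_extra, i, 2), 10L), 0L)
  lb_start <- recruit - config$pbs_lookback_days
  dm_rows <- slot_dates(seed, S$pbs_dm_date, ids, n_dm, 16L,
                        lb_start, recruit - 1L)
  dmi <- match(dm_rows$participant_id, ids)
  cls_u <- r_unif(seed, S$pbs_dm_class, slot_index(dmi, dm_rows$slot, 16L))
  dm_rows$class <- ifelse(!diabetic[dmi], "biguanide",
                   ifelse(ins_report[dmi] & cls_u < 0.45, "insulin",
                   ifelse(cls_u < 0.80, "biguanide", "sulphonylurea")))
  n_bg <- r_pois(seed, S$pbs_bg, i, params$pbs_background_rate)
  bg_rows <- slot_dates(seed, S$pbs_bg_date, ids, n_bg, CLAIM_SLOT_CAP,
                        lb_start, recruit - 1L)
  bg_rows$class <- "non_diabetes"
  pbs <- rbind(dm_rows[, c("participant_id", "date", "class")],
               bg_rows[, c("participant_id", "date", "class")])
  pbs <- data.frame(participant_id = pbs$participant_id,
                    supply_date = pbs$date,
                    medication_class = pbs$class,
                    stringsAsFactors = FALSE)
  pbs <- pbs[order(pbs$participant_id, pbs$supply_date,
                   pbs$medication_class), , drop = FALSE]
  rownames(pbs) <- NULL

  linkage <- data.frame(
    participant_id = ids,
    linked_apdc = r_bern(seed, S$link_apdc, i, params$link_prob),
    linked_medicare = r_bern(seed, S$link_medicare, i, params$link_prob),
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    participant_id = ids,
    true_status = ifelse(diabetic, "diabetes", "non_diabetes"),
    true_type = true_type,
    stringsAsFactors = FALSE
  )

  structure(list(questionnaire = questionnaire, admissions = admissions,
                 mbs = mbs, pbs = pbs, linkage = linkage, truth = truth),
            class = "dm_cohort", params = params)
}

#' Closed-form expected agreement statistics under the generator model
#'
#' Computes, by the law of total probability over true status, response
#' path and administrative outcome, the expected 2x2 cell fractions and
#' the expected sensitivity, specificity and predictive values of
#' self-report against the chosen criterion standard when a cohort is
#' generated by [simulate_cohort()]. The generator makes the
#' administrative outcome and the analysis-subset inclusion independent of
#' the questionnaire response given true status, which is what makes these
#' expectations available in closed form; they are the oracle against
#' which pipeline runs on generated cohorts are checked.
#'
#' @param params a [generator_params()] object.
#' @param source `"apdc"`, `"mbs"` or `"pbs"`.
#' @param config a [window_config()] (supplies the HbA1c counting span
#'   and claim threshold).
#' @return a list with elements `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `kappa` and `cells` (expected per-participant probabilities of
#'   the four 2x2 cells, not conditioned on inclusion).
#' @export
expected_stats <- function(params, source = c("apdc", "mbs", "pbs"),
                           config = window_config()) {
  stopifnot(inherits(params, "generator_params"))
  source <- match.arg(source)
  w1 <- params$type1_fraction
  # self-report path probabilities by true status (mixing over type)
  silent1 <- (1 - params$tick_sens) * (1 - params$free_text_rate) *
    (1 - params$insulin_given_type1)
  silent2 <- (1 - params$tick_sens) * (1 - params$free_text_rate) *
    (1 - params$insulin_given_type2)
  silent <- w1 * silent1 + (1 - w1) * silent2
  p_rep_d_S1 <- 1 - silent
  p_rep_u_S1 <- silent * params$oha_given_diabetes
  p_rep_n_S1 <- silent * (1 - params$oha_given_diabetes)
  p_rep_d_S0 <- 1 - params$tick_spec
  p_rep_u_S0 <- params$tick_spec * params$uncertain_text_rate
  p_rep_n_S0 <- params$tick_spec * (1 - params$uncertain_text_rate)

  if (source == "apdc") {
    incl1 <- params$link_prob * params$admit_prob
    incl0 <- incl1
    c1 <- params$code_sens
    c0 <- 1 - params$code_spec
  } else if (source == "mbs") {
    incl1 <- params$link_prob
    incl0 <- incl1
    span <- config$hba1c_years[2] - config$hba1c_years[1] + 1
    c1 <- 1 - stats::ppois(config$hba1c_min_claims - 1,
                           span * params$hba1c_rate_diabetes)
    c0 <- 1 - stats::ppois(config$hba1c_min_claims - 1,
                           span * params$hba1c_rate_other)
  } else {
    p_any1 <- 1 - (1 - params$pbs_claim_sens) *
      exp(-params$pbs_background_rate)
    p_any0 <- 1 - (1 - params$pbs_claim_fpr) *
      exp(-params$pbs_background_rate)
    incl1 <- params$link_prob * (1 - params$dva_prob) * p_any1
    incl0 <- params$link_prob * (1 - params$dva_prob) * p_any0
    c1 <- params$pbs_claim_sens / p_any1
    c0 <- params$pbs_claim_fpr / p_any0
  }

  pi1 <- params$prevalence
  m1 <- pi1 * incl1        # mass of included true diabetics
  m0 <- (1 - pi1) * incl0  # mass of included non-diabetics
  cells <- c(
    tp = m1 * p_rep_d_S1 * c1 + m0 * p_rep_d_S0 * c0,
    fp = m1 * p_rep_d_S1 * (1 - c1) + m0 * p_rep_d_S0 * (1 - c0),
    fn = m1 * p_rep_n_S1 * c1 + m0 * p_rep_n_S0 * c0,
    tn = m1 * p_rep_n_S1 * (1 - c1) + m0 * p_rep_n_S0 * (1 - c0)
  )
  tot <- sum(cells)
  p_o <- (cells["tp"] + cells["tn"]) / tot
  p_e <- ((cells["tp"] + cells["fp"]) * (cells["tp"] + cells["fn"]) +
            (cells["fn"] + cells["tn"]) * (cells["fp"] + cells["tn"])) / tot^2
  list(
    sensitivity = unname(cells["tp"] / (cells["tp"] + cells["fn"])),
    specificity = unname(cells["tn"] / (cells["fp"] + cells["tn"])),
    ppv = unname(cells["tp"] / (cells["tp"] + cells["fp"])),
    npv = unname(cells["tn"] / (cells["fn"] + cells["tn"])),
    kappa = unname((p_o - p_e) / (1 - p_e)),
    cells = cells
  )
}
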