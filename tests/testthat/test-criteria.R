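cfg <- window_config()

test_that("hospital criterion includes, excludes and scores participants correctly", {
  q <- rbind(
    q_row("P1", diabetes_tickbox = TRUE, age_at_diagnosis = 50L),  # coded
    q_row("P2"),                                 # admitted, no diabetes code
    q_row("P3"),                                 # not linked
    q_row("P4"),                                 # never admitted
    q_row("P5", diabetes_tickbox = TRUE, age_at_diagnosis = 57L),
    # P5: diagnosis year 1950+57 = 2007, last admission 2005 -> excluded
    q_row("P6", sex = "female"),                 # gestational codes only
    q_row("P7", diabetes_tickbox = TRUE)         # admission outside window
  )
  adm <- rbind(
    adm_row("P1", "2007-03-01", "I10;E11.9"),
    adm_row("P2", "2006-05-20", "I21.0"),
    adm_row("P3", "2007-01-01", "E10.1"),
    adm_row("P5", "2005-08-09", "I10"),
    adm_row("P6", "2004-02-11", "O24.1;I10"),
    adm_row("P7", "1999-12-31", "E11.9")
  )
  link <- data.frame(participant_id = q$participant_id,
                     linked_apdc = q$participant_id != "P3",
                     linked_medicare = TRUE, stringsAsFactors = FALSE)
  co <- make_cohort(q, admissions = adm, linkage = link)
  a <- suppressMessages(phenotype_cohort(co$questionnaire))
  expect_warning(res <- suppressMessages(apdc_criterion(co, a, cfg)),
                 "outside the extraction window")
  r <- function(id, col) res[res$participant_id == id, col]
  expect_true(r("P1", "included"));  expect_true(r("P1", "criterion_positive"))
  expect_true(r("P2", "included"));  expect_false(r("P2", "criterion_positive"))
  expect_equal(r("P3", "exclusion_reason"), "not_linked")
  expect_equal(r("P4", "exclusion_reason"), "no_admission")
  expect_equal(r("P5", "exclusion_reason"), "diagnosed_after_last_admission")
  expect_equal(r("P6", "exclusion_reason"), "gestational_only")
  expect_equal(r("P7", "exclusion_reason"), "no_admission")
  expect_true(all(is.na(res$criterion_positive[!res$included])))
  expect_equal(r("P1", "apdc_type"), "type2")
  expect_equal(r("P2", "apdc_type"), "no_diabetes_code")
})

test_that("hospital-record typing follows the E10 > E11 > E13/O24 > E14 precedence on every code subset", {
  pool <- c("E10.9", "E11.2", "E13.1", "O24.2", "E14", "I10")
  # independent oracle: first matching category in precedence order
  oracle <- function(codes) {
    if (any(startsWith(codes, "E10"))) return("type1")
    if (any(startsWith(codes, "E11"))) return("type2")
    if (any(startsWith(codes, "E13")) || any(startsWith(codes, "O24")))
      return("gestational_other")
    if (any(startsWith(codes, "E14"))) return("unspecified")
    "no_diabetes_code"
  }
  for (k in 0:(2^length(pool) - 1)) {
    codes <- pool[bitwAnd(k, 2^(seq_along(pool) - 1)) > 0]
    adm <- if (length(codes) == 0) {
      adm_row("X", "2007-01-01", "Z99.9")  # admission with no pool codes
    } else {
      adm_row(rep("X", length(codes)), "2007-01-01", codes)
    }
    got <- apdc_type(adm)$apdc_type
    want <- if (length(codes) == 0) "no_diabetes_code" else oracle(codes)
    expect_equal(got, want, info = paste(codes, collapse = "+"))
  }
})

test_that("HbA1c criterion applies the claim threshold and counting window", {
  q <- rbind(q_row("P1"), q_row("P2"), q_row("P3"), q_row("P4"))
  mbs <- rbind(
    mbs_row("P1", "2006-04-01"),
    mbs_row("P2", "2004-06-01"),              # extraction year, not counted
    mbs_row("P3", "2006-01-01"), mbs_row("P3", "2008-09-01"),
    mbs_row("P4", "2007-01-01", item_number = 23L)  # not an HbA1c item
  )
  co <- make_cohort(q, mbs = mbs)
  a <- suppressMessages(phenotype_cohort(co$questionnaire))

  r1 <- suppressMessages(mbs_criterion(co, a, cfg))
  expect_equal(r1$criterion_positive, c(TRUE, FALSE, TRUE, FALSE))

  cfg2 <- window_config(hba1c_min_claims = 2)
  r2 <- suppressMessages(mbs_criterion(co, a, cfg2))
  expect_equal(r2$criterion_positive, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("HbA1c criterion excludes unlinked participants and late diagnoses", {
  q <- rbind(q_row("P1"),
             q_row("P2", diabetes_tickbox = TRUE, age_at_diagnosis = 58L))
  link <- data.frame(participant_id = c("P1", "P2"),
                     linked_apdc = TRUE,
                     linked_medicare = c(FALSE, TRUE), stringsAsFactors = FALSE)
  co <- make_cohort(q, linkage = link)
  a <- suppressMessages(phenotype_cohort(co$questionnaire))
  # narrow counting window ending before P2's diagnosis year (1950+58=2008)
  cfg3 <- window_config(hba1c_years = c(2005, 2007))
  r <- suppressMessages(mbs_criterion(co, a, cfg3))
  expect_equal(r$exclusion_reason, c("not_linked", "diagnosis_after_window"))
  expect_false(any(r$included))
})

test_that("dispensing criterion uses the look-back window, DVA and claims-history rules", {
  q <- rbind(
    q_row("P1"),                    # insulin claim 30 days before recruitment
    q_row("P2", dva_card = TRUE),   # veteran card -> excluded
    q_row("P3"),                    # statins only -> included, negative
    q_row("P4"),                    # no claims at all -> excluded
    q_row("P5"),                    # diabetes claim outside look-back
    q_row("P6")                     # claim on recruitment day: not look-back
  )
  recruit <- q$recruitment_date[1]
  pbs <- rbind(
    pbs_row("P1", recruit - 30, "insulin"),
    pbs_row("P2", recruit - 10, "insulin"),
    pbs_row("P3", recruit - 100, "non_diabetes"),
    pbs_row("P5", recruit - 400, "biguanide"),
    pbs_row("P5", recruit - 50, "non_diabetes"),
    pbs_row("P6", recruit, "biguanide")
  )
  co <- make_cohort(q, pbs = pbs)
  a <- suppressMessages(phenotype_cohort(co$questionnaire))
  r <- suppressMessages(pbs_criterion(co, a, cfg))
  expect_equal(r$exclusion_reason,
               c("none", "dva_card", "none", "no_pbs_claims",
                 "none", "no_pbs_claims"))
  expect_equal(r$criterion_positive[r$included], c(TRUE, FALSE, FALSE))
})

test_that("exclusion accounting is exhaustive and shrinking windows never creates positives", {
  co <- suppressMessages(simulate_cohort(generator_params(n = 4000, seed = 9)))
  a <- suppressMessages(phenotype_cohort(co$questionnaire))
  for (f in list(apdc_criterion, mbs_criterion, pbs_criterion)) {
    r <- suppressMessages(f(co, a, cfg))
    expect_equal(nrow(r), nrow(co$questionnaire))
    expect_equal(sum(r$included) + sum(r$exclusion_reason != "none"), nrow(r))
    expect_true(all(r$exclusion_reason[r$included] == "none"))
  }
  # threshold 2 positives are a subset of threshold 1 positives
  m1 <- suppressMessages(mbs_criterion(co, a, window_config(hba1c_min_claims = 1)))
  m2 <- suppressMessages(mbs_criterion(co, a, window_config(hba1c_min_claims = 2)))
  expect_true(all(which(m2$included & m2$criterion_positive) %in%
                    which(m1$included & m1$criterion_positive)))
  # half-year look-back positives are a subset of full-year positives
  p1 <- suppressMessages(pbs_criterion(co, a, cfg))
  p2 <- suppressMessages(pbs_criterion(co, a, window_config(pbs_lookback_days = 180)))
  expect_true(all(which(p2$included & p2$criterion_positive) %in%
                    which(p1$included & p1$criterion_positive)))
  # a hospital-record type implies a positive hospital criterion
  ap <- suppressMessages(apdc_criterion(co, a, cfg))
  expect_true(all(ap$criterion_positive[ap$included &
                                          ap$apdc_type == "type1"]))
})
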