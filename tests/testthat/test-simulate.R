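test_that("the generator is reproducible byte-for-byte and extendable", {
  p <- generator_params(n = 400, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(p), d1)
  write_cohort(simulate_cohort(p), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # enlarging the cohort leaves the first participants untouched
  big <- simulate_cohort(generator_params(n = 800, seed = 99))
  small <- simulate_cohort(p)
  expect_identical(small$questionnaire, big$questionnaire[1:400, ])
  expect_identical(small$truth, big$truth[1:400, ])
  keep <- big$admissions$participant_id %in% small$questionnaire$participant_id
  expect_identical(small$admissions, big$admissions[keep, ],
                   ignore_attr = "row.names")
})

test_that("degenerate parameters behave as specified", {
  p0 <- generator_params(n = 2000, seed = 4, prevalence = 0)
  co <- simulate_cohort(p0)
  expect_true(all(co$truth$true_status == "non_diabetes"))
  a <- suppressMessages(phenotype_cohort(co$questionnaire))
  # only route into the diabetes group is a false-positive tick
  expect_true(all(a$evidence[a$status == "diabetes"] == "tickbox"))

  expect_error(generator_params(prevalence = 1.2), "prevalence")
  expect_error(generator_params(code_sens = -0.1), "code_sens")
  expect_error(generator_params(n = 0), ": n")
  expect_error(generator_params(hba1c_rate_other = -1), "hba1c_rate_other")
})

test_that("generated records satisfy the data-model invariants", {
  co <- simulate_cohort(generator_params(n = 1500, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_silent(suppressMessages(read_cohort(dir)))  # validators accept all rows
  q <- co$questionnaire
  age <- as.integer(format(q$recruitment_date, "%Y")) - q$year_of_birth
  expect_true(all(is.na(q$age_at_diagnosis) |
                    (q$age_at_diagnosis >= 0 & q$age_at_diagnosis <= age)))
  expect_true(all(is.na(q$age_at_last_delivery) | q$sex == "female"))
  expect_true(all(nchar(co$admissions$diagnosis_codes) > 0))
})

test_that("closed-form expectations are exact in the noiseless and single-noise limits", {
  perfect <- generator_params(
    tick_sens = 1, tick_spec = 1, free_text_rate = 0, uncertain_text_rate = 0,
    insulin_given_type1 = 0, insulin_given_type2 = 0, oha_given_diabetes = 0,
    code_sens = 1, code_spec = 1, pbs_claim_sens = 1, pbs_claim_fpr = 0,
    hba1c_rate_other = 0)
  e <- expected_stats(perfect, "apdc")
  expect_equal(e$sensitivity, 1)
  expect_equal(e$specificity, 1)
  expect_equal(e$ppv, 1)
  expect_equal(e$npv, 1)
  e_pbs <- expected_stats(perfect, "pbs")
  expect_equal(e_pbs$sensitivity, 1)
  expect_equal(e_pbs$specificity, 1)

  # with the tick box as the only noise source, expected sensitivity = tick_sens
  s <- 0.8
  single <- generator_params(
    tick_sens = s, tick_spec = 1, free_text_rate = 0, uncertain_text_rate = 0,
    insulin_given_type1 = 0, insulin_given_type2 = 0, oha_given_diabetes = 0,
    code_sens = 1, code_spec = 1)
  expect_equal(expected_stats(single, "apdc")$sensitivity, s)
  expect_equal(expected_stats(single, "apdc")$specificity, 1)
})

test_that("closed-form expectations match a Monte-Carlo pipeline run", {
  p <- generator_params(n = 30000, seed = 17)
  co <- simulate_cohort(p)
  v <- suppressMessages(run_validation(co))
  for (s in c("apdc", "mbs", "pbs")) {
    e <- expected_stats(p, s)
    tb <- v$tables[[s]]
    st <- v$stats[[s]]
    se_sens <- sqrt(e$sensitivity * (1 - e$sensitivity) / (tb$tp + tb$fn))
    se_spec <- sqrt(e$specificity * (1 - e$specificity) / (tb$fp + tb$tn))
    expect_lt(abs(st$sensitivity - e$sensitivity), 3 * se_sens,
              label = paste(s, "sensitivity deviation"))
    expect_lt(abs(st$specificity - e$specificity), 3 * se_spec,
              label = paste(s, "specificity deviation"))
  }
})

test_that("generated uncertain-path participants are routed to uncertain", {
  co <- simulate_cohort(generator_params(n = 8000, seed = 23,
                                         uncertain_text_rate = 0.01))
  a <- suppressMessages(phenotype_cohort(co$questionnaire))
  q <- co$questionnaire
  idx <- match(q$participant_id, a$participant_id)
  uncertain_phrases <- c("borderline diabetes", "pre-diabetes",
                         "diabetes insipidus", "impaired glucose tolerance")
  wrote_unc <- !q$diabetes_tickbox & q$other_illness_text %in% uncertain_phrases
  expect_true(all(a$status[idx][wrote_unc] == "uncertain"))
  oha_only <- !q$diabetes_tickbox & q$other_illness_text == "" &
    q$metformin_tickbox & q$medication_text == ""
  expect_true(any(oha_only))
  expect_true(all(a$status[idx][oha_only] == "uncertain"))
})
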