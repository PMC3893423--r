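lex <- default_lexicons()

test_that("free-text diagnosis matching is case-insensitive, whole-phrase, with uncertain precedence", {
  got <- match_free_text_diagnosis(
    c("sugar diabetes", "Diabetes Insipidus", "", "hypertension",
      "SUGAR   diabetes", "diabetic foot", "borderline diabetes",
      "asthma and diabetes type 2"),
    lex$diagnosis)
  expect_equal(got, c("diabetes", "uncertain", "none", "none",
                      "diabetes", "none", "uncertain", "diabetes"))
})

test_that("a text matching both an uncertain and a positive pattern is uncertain", {
  # every packaged uncertain phrase embedded in otherwise-positive text
  unc <- lex$diagnosis$term[lex$diagnosis$category == "uncertain"]
  for (term in unc) {
    expect_equal(
      match_free_text_diagnosis(paste("diabetes and", term), lex$diagnosis),
      "uncertain")
  }
})

test_that("adding an uncertain term never promotes a participant to diabetes", {
  texts <- c("diabetes", "sugar diabetes", "gout", "pre-diabetes",
             "maybe diabetes", "diabetes possible", "")
  before <- match_free_text_diagnosis(texts, lex$diagnosis)
  wider <- lex$diagnosis
  wider <- rbind(wider, data.frame(term = "maybe diabetes",
                                   category = "uncertain"))
  class(wider) <- class(lex$diagnosis)
  after <- match_free_text_diagnosis(texts, wider)
  # a result may move towards uncertain, never from uncertain to diabetes
  expect_false(any(before == "uncertain" & after == "diabetes"))
  expect_true(all(after[before == "diabetes"] %in% c("diabetes", "uncertain")))
  expect_equal(after[texts == "maybe diabetes"], "uncertain")
})

test_that("medication matching combines the metformin tick box with lexicon hits", {
  got <- match_medication_text(c("", "insulin twice daily", "", "Lantus and metformin"),
                               c(TRUE, FALSE, FALSE, FALSE), lex$medication)
  expect_equal(got$insulin, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(got$oha, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(got$classes[[1]], "biguanide")
  expect_equal(got$classes[[2]], "insulin")
  expect_equal(got$classes[[3]], character(0))
  expect_equal(got$classes[[4]], c("biguanide", "insulin"))
})

test_that("lexicon readers enforce the closed class set and required entries", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term,class", "foo,laxative"), tmp)
  expect_error(read_medication_lexicon(tmp), "unknown medication class")
  writeLines(c("term,class", "metformin,biguanide"), tmp)
  expect_error(read_medication_lexicon(tmp), "tick-box products")
  writeLines(c("term,class", "Insulin,insulin", "insulin,insulin"), tmp)
  expect_error(read_medication_lexicon(tmp), "duplicate")
  writeLines(c("term,category", "diabetes,maybe"), tmp)
  expect_error(read_diagnosis_lexicon(tmp), "diabetes.*uncertain")
})

test_that("status assignment follows the tick-box > free-text > medication order", {
  # tick box outranks an uncertain free text
  a <- assign_status(q_row(diabetes_tickbox = TRUE,
                           other_illness_text = "borderline diabetes"), lex)
  expect_equal(a$status, "diabetes")
  expect_equal(a$evidence, "tickbox")

  # insulin-only reporters join the diabetes group
  b <- assign_status(q_row(medication_text = "insulin"), lex)
  expect_equal(b$status, "diabetes")
  expect_equal(b$evidence, "insulin_text")
  expect_true(b$self_reported_insulin)

  # OHA-only reporters are uncertain
  d <- assign_status(q_row(metformin_tickbox = TRUE), lex)
  expect_equal(d$status, "uncertain")
  expect_equal(d$evidence, "oha_text")

  # free-text diabetes without the tick box
  e <- assign_status(q_row(other_illness_text = "sugar diabetes"), lex)
  expect_equal(e$status, "diabetes")
  expect_equal(e$evidence, "free_text")

  # nothing reported
  f <- assign_status(q_row(), lex)
  expect_equal(f$status, "non_diabetes")
  expect_equal(f$evidence, "none")
  expect_equal(f$diabetes_type, "not_applicable")
})

test_that("insulin text outranks the uncertain OHA-only route", {
  a <- assign_status(q_row(medication_text = "lantus", metformin_tickbox = TRUE),
                     lex)
  expect_equal(a$status, "diabetes")
  expect_equal(a$evidence, "insulin_text")
  expect_true(a$self_reported_oha)
})

test_that("phenotyping partitions the cohort and is deterministic", {
  co <- suppressMessages(simulate_cohort(generator_params(n = 2000, seed = 11)))
  a1 <- suppressMessages(phenotype_cohort(co$questionnaire, lex))
  a2 <- suppressMessages(phenotype_cohort(co$questionnaire, lex))
  expect_identical(a1, a2)
  expect_equal(nrow(a1), nrow(co$questionnaire))
  expect_true(all(a1$status %in% c("diabetes", "non_diabetes", "uncertain")))
  counts <- attr(a1, "counts")
  expect_equal(sum(counts), nrow(a1))
  expect_equal(attr(a1, "prevalence"), mean(a1$status == "diabetes"))
  # status = diabetes only via the three diabetes evidence paths
  expect_true(all(a1$evidence[a1$status == "diabetes"] %in%
                    c("tickbox", "free_text", "insulin_text")))
  expect_true(all(a1$evidence[a1$status == "non_diabetes"] == "none"))
})

test_that("an empty cohort yields an empty assignment with undefined prevalence", {
  empty <- q_row()[0, ]
  expect_warning(a <- phenotype_cohort(empty, lex), "prevalence undefined")
  expect_equal(nrow(a), 0)
  expect_true(is.na(attr(a, "prevalence")))
})
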