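# CSV data model shared by all pipeline stages.
#
# Dialect: comma-separated, UTF-8, mandatory header, ISO-8601 dates,
# missing values written as the empty string. One hospital admission per
# row, with its diagnosis-code list serialised as a single
# semicolon-delimited field (first code = principal diagnosis).

ICD_CODE_PATTERN <- "^[A-Z][0-9]{2}(\\.[0-9]+)?$"

stop_row <- function(file, rows, msg) {
  stop(sprintf("%s: row %s: %s", file, paste(rows, collapse = ", "), msg),
       call. = FALSE)
}

read_table_file <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x
}

parse_date <- function(x, file, col) {
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  has <- nzchar(x)
  parsed <- as.Date(x[has], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    stop_row(file, which(has)[is.na(parsed)][1] + 1L,
             sprintf("invalid ISO-8601 date in '%s'", col))
  }
  out[has] <- parsed
  out
}

parse_bool <- function(x, file, col, allow_missing = FALSE) {
  x <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- is.na(out) & nzchar(x)
  if (any(bad)) {
    stop_row(file, which(bad)[1] + 1L, sprintf("invalid boolean in '%s'", col))
  }
  if (!allow_missing && anyNA(out)) {
    stop_row(file, which(is.na(out))[1] + 1L,
             sprintf("missing value not allowed in '%s'", col))
  }
  out
}

parse_int <- function(x, file, col, allow_missing = TRUE) {
  out <- rep(NA_integer_, length(x))
  has <- nzchar(trimws(x))
  suppressWarnings(v <- as.integer(x[has]))
  if (anyNA(v)) {
    stop_row(file, which(has)[is.na(v)][1] + 1L,
             sprintf("invalid integer in '%s'", col))
  }
  out[has] <- v
  if (!allow_missing && anyNA(out)) {
    stop_row(file, which(is.na(out))[1] + 1L,
             sprintf("missing value not allowed in '%s'", col))
  }
  out
}

validate_questionnaire <- function(q, file) {
  out <- data.frame(
    participant_id = trimws(q$participant_id),
    recruitment_date = parse_date(q$recruitment_date, file, "recruitment_date"),
    sex = trimws(q$sex),
    year_of_birth = parse_int(q$year_of_birth, file, "year_of_birth",
                              allow_missing = FALSE),
    diabetes_tickbox = parse_bool(q$diabetes_tickbox, file, "diabetes_tickbox",
                                  allow_missing = TRUE),
    age_at_diagnosis = parse_int(q$age_at_diagnosis, file, "age_at_diagnosis"),
    other_illness_text = q$other_illness_text,
    metformin_tickbox = parse_bool(q$metformin_tickbox, file,
                                   "metformin_tickbox"),
    medication_text = q$medication_text,
    dva_card = parse_bool(q$dva_card, file, "dva_card"),
    age_at_last_delivery = parse_int(q$age_at_last_delivery, file,
                                     "age_at_last_delivery"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$participant_id)) {
    dup <- which(duplicated(out$participant_id))[1]
    stop_row(file, dup + 1L,
             sprintf("duplicate participant_id '%s'", out$participant_id[dup]))
  }
  bad_sex <- !out$sex %in% c("female", "male")
  if (any(bad_sex)) stop_row(file, which(bad_sex)[1] + 1L, "sex must be 'female' or 'male'")
  if (anyNA(out$recruitment_date)) {
    stop_row(file, which(is.na(out$recruitment_date))[1] + 1L,
             "recruitment_date is required")
  }
  recruit_age <- as.integer(format(out$recruitment_date, "%Y")) - out$year_of_birth
  bad_age <- !is.na(out$age_at_diagnosis) &
    (out$age_at_diagnosis < 0 | out$age_at_diagnosis > recruit_age)
  if (any(bad_age)) {
    stop_row(file, which(bad_age)[1] + 1L,
             "age_at_diagnosis outside [0, age at recruitment]")
  }
  bad_del <- !is.na(out$age_at_last_delivery) & out$sex != "female"
  if (any(bad_del)) {
    stop_row(file, which(bad_del)[1] + 1L,
             "age_at_last_delivery present for non-female participant")
  }
  out
}

validate_admissions <- function(a, file) {
  out <- data.frame(
    participant_id = trimws(a$participant_id),
    admission_date = parse_date(a$admission_date, file, "admission_date"),
    diagnosis_codes = trimws(a$diagnosis_codes),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) return(out)
  if (anyNA(out$admission_date)) {
    stop_row(file, which(is.na(out$admission_date))[1] + 1L,
             "admission_date is required")
  }
  codes <- strsplit(out$diagnosis_codes, ";", fixed = TRUE)
  empty <- vapply(codes, function(cc) length(cc) == 0 || all(!nzchar(trimws(cc))),
                  logical(1))
  if (any(empty)) {
    stop_row(file, which(empty)[1] + 1L, "diagnosis_codes must be non-empty")
  }
  bad <- vapply(codes, function(cc) {
    cc <- toupper(trimws(cc))
    any(!grepl(ICD_CODE_PATTERN, cc))
  }, logical(1))
  if (any(bad)) {
    stop_row(file, which(bad)[1] + 1L,
             "diagnosis code does not match the ICD-10-AM pattern")
  }
  out$diagnosis_codes <- vapply(
    codes, function(cc) paste(toupper(trimws(cc)), collapse = ";"), character(1))
  out
}

validate_mbs <- function(m, file) {
  out <- data.frame(
    participant_id = trimws(m$participant_id),
    service_date = parse_date(m$service_date, file, "service_date"),
    item_number = parse_int(m$item_number, file, "item_number",
                            allow_missing = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(out) > 0 && anyNA(out$service_date)) {
    stop_row(file, which(is.na(out$service_date))[1] + 1L,
             "service_date is required")
  }
  out
}

validate_pbs <- function(p, file) {
  out <- data.frame(
    participant_id = trimws(p$participant_id),
    supply_date = parse_date(p$supply_date, file, "supply_date"),
    medication_class = trimws(p$medication_class),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) return(out)
  if (anyNA(out$supply_date)) {
    stop_row(file, which(is.na(out$supply_date))[1] + 1L,
             "supply_date is required")
  }
  bad <- !out$medication_class %in% MEDICATION_CLASSES
  if (any(bad)) {
    stop_row(file, which(bad)[1] + 1L,
             sprintf("medication_class '%s' not in the closed class set",
                     out$medication_class[which(bad)[1]]))
  }
  out
}

validate_linkage <- function(l, file) {
  data.frame(
    participant_id = trimws(l$participant_id),
    linked_apdc = parse_bool(l$linked_apdc, file, "linked_apdc"),
    linked_medicare = parse_bool(l$linked_medicare, file, "linked_medicare"),
    stringsAsFactors = FALSE
  )
}

#' Read a linked study cohort from CSV files
#'
#' Reads and validates the five delimited-text inputs of the pipeline:
#' baseline questionnaire records, hospital admission records with
#' ICD-10-AM diagnosis-code lists, medical-service (HbA1c) claims, pharmacy
#' dispensing claims, and per-participant linkage flags. Rows violating a
#' type invariant are rejected with a diagnostic naming the file and row.
#'
#' @param dir directory containing `questionnaire.csv`, `admissions.csv`,
#'   `mbs_claims.csv`, `pbs_claims.csv` and `linkage.csv`. Individual
#'   locations can be overridden via `paths`.
#' @param paths optional named list overriding individual file paths
#'   (`questionnaire`, `admissions`, `mbs`, `pbs`, `linkage`).
#' @return an object of class `dm_cohort`: a list with validated data
#'   frames `questionnaire`, `admissions`, `mbs`, `pbs`, `linkage` (and
#'   `truth`, when a `truth.csv` file is present beside the others).
#' @export
read_cohort <- function(dir = NULL, paths = list()) {
  defaults <- list(questionnaire = "questionnaire.csv",
                   admissions = "admissions.csv",
                   mbs = "mbs_claims.csv",
                   pbs = "pbs_claims.csv",
                   linkage = "linkage.csv")
  files <- lapply(names(defaults), function(nm) {
    if (!is.null(paths[[nm]])) paths[[nm]] else file.path(dir, defaults[[nm]])
  })
  names(files) <- names(defaults)

  q <- validate_questionnaire(
    read_table_file(files$questionnaire,
                    c("participant_id", "recruitment_date", "sex",
                      "year_of_birth", "diabetes_tickbox", "age_at_diagnosis",
                      "other_illness_text", "metformin_tickbox",
                      "medication_text", "dva_card", "age_at_last_delivery")),
    files$questionnaire)
  a <- validate_admissions(
    read_table_file(files$admissions,
                    c("participant_id", "admission_date", "diagnosis_codes")),
    files$admissions)
  m <- validate_mbs(
    read_table_file(files$mbs,
                    c("participant_id", "service_date", "item_number")),
    files$mbs)
  p <- validate_pbs(
    read_table_file(files$pbs,
                    c("participant_id", "supply_date", "medication_class")),
    files$pbs)
  l <- validate_linkage(
    read_table_file(files$linkage,
                    c("participant_id", "linked_apdc", "linked_medicare")),
    files$linkage)

  if (anyDuplicated(l$participant_id)) {
    stop(files$linkage, ": duplicate participant_id in linkage file",
         call. = FALSE)
  }
  if (!setequal(q$participant_id, l$participant_id)) {
    stop("linkage file must contain exactly one record per questionnaire ",
         "participant", call. = FALSE)
  }

  cohort <- list(questionnaire = q, admissions = a, mbs = m, pbs = p,
                 linkage = l)
  truth_path <- if (!is.null(dir)) file.path(dir, "truth.csv") else NULL
  if (!is.null(truth_path) && file.exists(truth_path)) {
    cohort$truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  }
  log_stage("read_cohort", nrow(q))
  structure(cohort, class = "dm_cohort")
}

fmt_col <- function(x) {
  if (inherits(x, "Date")) {
    ifelse(is.na(x), "", format(x, "%Y-%m-%d"))
  } else if (is.logical(x)) {
    ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
  } else {
    ifelse(is.na(x), "", as.character(x))
  }
}

write_csv_canonical <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_col), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
}

#' Write a cohort bundle to CSV files
#'
#' Inverse of [read_cohort()]: writes the record collections in the
#' canonical CSV dialect (ISO dates, `TRUE`/`FALSE` booleans, empty string
#' for missing). A write followed by a read reproduces every field.
#'
#' @param cohort a `dm_cohort` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory written to.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_csv_canonical(cohort$questionnaire, file.path(dir, "questionnaire.csv"))
  write_csv_canonical(cohort$admissions, file.path(dir, "admissions.csv"))
  write_csv_canonical(cohort$mbs, file.path(dir, "mbs_claims.csv"))
  write_csv_canonical(cohort$pbs, file.path(dir, "pbs_claims.csv"))
  write_csv_canonical(cohort$linkage, file.path(dir, "linkage.csv"))
  if (!is.null(cohort$truth)) {
    write_csv_canonical(cohort$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' @export
print.dm_cohort <- function(x, ...) {
  cat("Linked study cohort\n")
  cat(sprintf("  questionnaire: %d participants\n", nrow(x$questionnaire)))
  cat(sprintf("  admissions:    %d records\n", nrow(x$admissions)))
  cat(sprintf("  MBS claims:    %d records\n", nrow(x$mbs)))
  cat(sprintf("  PBS claims:    %d records\n", nrow(x$pbs)))
  if (!is.null(x$truth)) cat("  ground truth present\n")
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' Loads a YAML (or JSON) configuration holding the validation windows and
#' thresholds understood by [window_config()] and, optionally, a
#' `generator` block of [generator_params()] overrides.
#'
#' @param path path to a YAML file.
#' @return a list with elements `windows` (a `window_config`) and
#'   `generator` (a named list of generator overrides, possibly empty).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  windows <- do.call(window_config, cfg$windows %||% list())
  list(windows = windows, generator = cfg$generator %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
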