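#' Read a medication lexicon
#'
#' A medication lexicon maps lower-cased product or keyword strings (brand
#' and generic names of insulin products and oral hypoglycaemic agents) to a
#' medication class. The packaged default covers the insulin and OHA
#' products marketed in Australia during the cohort recruitment period; the
#' CSV file, not the code, is the source of truth and can be extended with
#' further brand names or misspelling variants.
#'
#' @param path path to a CSV file with columns `term` and `class`. Defaults
#'   to the lexicon shipped with the package.
#' @return a data frame of class `medication_lexicon` with columns `term`
#'   (lower-cased, unique) and `class` (one of the closed medication-class
#'   set).
#' @export
#' @examples
#' lex <- read_medication_lexicon()
#' head(lex)
read_medication_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "medication_lexicon.csv",
                        package = "diablink", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("medication lexicon file not found: ", path)
  lex <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("term", "class") %in% names(lex))) {
    stop("medication lexicon must have columns 'term' and 'class'")
  }
  lex$term <- tolower(trimws(lex$term))
  lex$class <- trimws(lex$class)
  if (anyDuplicated(lex$term)) {
    stop("duplicate lexicon terms after case-folding: ",
         paste(unique(lex$term[duplicated(lex$term)]), collapse = ", "))
  }
  bad <- setdiff(unique(lex$class), MEDICATION_CLASSES)
  if (length(bad) > 0) {
    stop("unknown medication class(es): ", paste(bad, collapse = ", "))
  }
  required <- c(diabex = "biguanide", diaformin = "biguanide",
                metformin = "biguanide", insulin = "insulin")
  have <- lex$class[match(names(required), lex$term)]
  if (any(is.na(have)) || any(have != required)) {
    stop("medication lexicon must contain at least the tick-box products ",
         "(diabex, diaformin, metformin -> biguanide) and the generic ",
         "'insulin' keyword")
  }
  class(lex) <- c("medication_lexicon", "data.frame")
  lex
}

#' Read a diagnosis (free-text illness) lexicon
#'
#' A diagnosis lexicon lists free-text phrases that indicate diabetes and
#' phrases that indicate an uncertain or non-prevalent diabetes state
#' (pre-diabetes, borderline diabetes, diabetes insipidus). Uncertain terms
#' take precedence at classification time, so phrases containing the word
#' "diabetes" can still route a participant to the uncertain group.
#'
#' @param path path to a CSV file with columns `term` and `category`
#'   (`diabetes` or `uncertain`). Defaults to the packaged lexicon.
#' @return a data frame of class `diagnosis_lexicon`.
#' @export
read_diagnosis_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diagnosis_lexicon.csv",
                        package = "diablink", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("diagnosis lexicon file not found: ", path)
  lex <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("term", "category") %in% names(lex))) {
    stop("diagnosis lexicon must have columns 'term' and 'category'")
  }
  lex$term <- tolower(trimws(lex$term))
  lex$category <- trimws(lex$category)
  bad <- setdiff(unique(lex$category), c("diabetes", "uncertain"))
  if (length(bad) > 0) {
    stop("diagnosis lexicon categories must be 'diabetes' or 'uncertain', ",
         "got: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(lex$term)) {
    stop("duplicate diagnosis lexicon terms: ",
         paste(unique(lex$term[duplicated(lex$term)]), collapse = ", "))
  }
  class(lex) <- c("diagnosis_lexicon", "data.frame")
  lex
}

#' Load the packaged default lexicons
#'
#' @param dir optional directory holding `medication_lexicon.csv` and
#'   `diagnosis_lexicon.csv`; defaults to the files shipped with the
#'   package.
#' @return a list with elements `medication` and `diagnosis`.
#' @export
default_lexicons <- function(dir = NULL) {
  if (is.null(dir)) {
    list(medication = read_medication_lexicon(),
         diagnosis = read_diagnosis_lexicon())
  } else {
    list(medication = read_medication_lexicon(
           file.path(dir, "medication_lexicon.csv")),
         diagnosis = read_diagnosis_lexicon(
           file.path(dir, "diagnosis_lexicon.csv")))
  }
}

# Normalise free text before matching: case-fold and collapse whitespace.
normalise_text <- function(text) {
  text <- tolower(ifelse(is.na(text), "", text))
  gsub("\\s+", " ", trimws(text))
}

# Whole-phrase regex for a lexicon term: word boundaries at both ends,
# internal whitespace flexible. "diabetes" must not match inside
# "diabetic", but does match as a word inside "diabetes insipidus".
term_pattern <- function(term) {
  esc <- gsub("([^[:alnum:] ])", "\\\\\\1", term)  # escape regex metachars
  esc <- gsub(" +", "\\\\s+", esc)
  paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])")
}

# Which of `terms` match each text? Returns an n x length(terms) logical
# matrix. Texts are normalised once; terms are assumed lower-case.
match_terms <- function(text, terms) {
  text <- normalise_text(text)
  out <- matrix(FALSE, nrow = length(text), ncol = length(terms))
  nonempty <- nzchar(text)
  if (any(nonempty) && length(terms) > 0) {
    for (j in seq_along(terms)) {
      out[nonempty, j] <- grepl(term_pattern(terms[j]), text[nonempty],
                                perl = TRUE)
    }
  }
  out
}
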