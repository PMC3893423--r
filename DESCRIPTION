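Package: diablink
Title: Rule-Based Diabetes Phenotyping and Validation Against Linked
    Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a rule-based algorithm for ascertaining diabetes
    status from baseline cohort questionnaires (diagnosis tick-box,
    free-text illness fields and medication fields matched against a
    packaged medication lexicon), a companion algorithm for classifying
    diabetes type (type 1, type 2, gestational/other), and a validation
    pipeline that compares self-report against three linked
    administrative criterion standards: hospital admission records with
    ICD-10-AM diabetes codes, medical-service claims for HbA1c testing,
    and pharmacy dispensing claims for diabetes medication. Agreement is
    summarised by sensitivity, specificity, predictive values and the
    two-rater kappa statistic. A synthetic linked-cohort generator with
    known ground truth and closed-form expected statistics allows every
    stage of the pipeline to be exercised and checked without access to
    restricted record-linkage data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
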