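---
title: "Phenotyping self-reported diabetes and validating it against linked administrative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping self-reported diabetes and validating it against linked administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(diablink)
```

## The problem

Population cohort studies typically ascertain chronic disease from a
self-administered baseline questionnaire. Self-report is cheap and covers
the whole cohort, but it misclassifies: people under-report conditions
they do not connect to the question, and over-report resolved ones (for
diabetes, notably gestational diabetes). When the cohort is linked to
administrative health collections — hospital admissions coded in
ICD-10-AM, universal-insurance claims for diagnostic tests, and pharmacy
dispensing claims — each linked source yields an independent, similarly
imperfect indicator of the same condition, and the agreement between
self-report and each source can be quantified.

`diablink` implements this workflow for diabetes as a reusable, testable
pipeline:

1. **Phenotyping** — a rule-based algorithm assigns every participant a
   status in {diabetes, non-diabetes, uncertain} from questionnaire
   fields alone.
2. **Typing** — a second rule set splits the diabetes group into type 1,
   type 2 and gestational/other.
3. **Criterion standards** — three administrative indicators are built,
   each with its own analysis subset (exclusion rules).
4. **Agreement** — 2×2 cross-tabulations and sensitivity, specificity,
   PPV, NPV and the two-rater kappa.
5. **Synthetic cohort** — a generator with known ground truth and
   closed-form expected statistics, so the full pipeline can be exercised
   and checked without access to restricted linked data.

## The phenotyping algorithm

Participants are evaluated in a fixed order; the first rule that fires
decides the status and records the evidence path:

1. An affirmative tick-box answer to "Has a doctor EVER told you that
   you have diabetes?" assigns **diabetes** (evidence `tickbox`).
2. Otherwise the free-text "other important illness" field is matched
   against a diagnosis lexicon. Positive phrases ("diabetes", "sugar
   diabetes", "type 2 diabetes", ...) assign **diabetes**
   (`free_text`); uncertain phrases ("pre-diabetes", "borderline
   diabetes", "diabetes insipidus") assign **uncertain**. Uncertain
   terms take precedence, which is what routes "diabetes insipidus" —
   a phrase containing the positive word "diabetes" — to uncertain.
3. Otherwise the medication fields are searched against a medication
   lexicon of insulin products and oral hypoglycaemic agents (OHA).
   Any insulin product assigns **diabetes** (`insulin_text`); OHA use
   alone (including the metformin-product tick box) assigns
   **uncertain** (`oha_text`), because OHAs — metformin in particular —
   are also prescribed outside diabetes.
4. Everything else is **non-diabetes**.

Matching is case-insensitive, whitespace-normalised and whole-phrase
with word boundaries: "diabetes" does not fire inside "diabetic". The
original analysts combined pattern matching with manual review of the
matched strings; the word-boundary rule is this package's deterministic
approximation of that manual step. There is deliberately no spelling
correction or fuzzy matching — misspellings are handled by adding
variants to the lexicon CSV, which (not the code) is the source of truth
for both lexicons.

```{r}
lex <- default_lexicons()
match_free_text_diagnosis(c("sugar diabetes", "diabetes insipidus",
                            "diabetic foot", "hypertension"), lex$diagnosis)
```

The algorithm detects *prevalent* diabetes at recruitment only; no
attempt is made to identify incident cases from later records.

## The typing algorithm

The questionnaire never asks the type of diabetes, so type is inferred,
in order: (1) an explicit free-text declaration of type 1, then (2) of
type 2; (3) insulin use with diagnosis before age 31 — implemented as
age at diagnosis ≤ 30, a strict reading of "before" — or with no age of
diagnosis given, assigns type 1; (4) women diagnosed before the age at
their last delivery with no current diabetes medication are
gestational/other; (5) the remainder are type 2.

Two genuinely open choices are resolved as follows. A free-text
declaration outranks the insulin/age rule when they conflict (a declared
type 2 on insulin diagnosed at 20 stays type 2); conflicts are counted
and reported rather than silently resolved. The gestational comparison
uses ages, because the questionnaire records ages rather than dates; a
tie (diagnosed in the year of the last delivery) is *not* gestational.

## Criterion standards

Each linked source defines a binary indicator on its own analysis
subset. All date windows are closed calendar-date intervals, configured
via `window_config()`:

| Source | Positive when | Default window | Exclusions (in precedence order) |
|---|---|---|---|
| Hospital (APDC) | any admission carries an ICD-10-AM code with prefix E10, E11, E13, E14 or O24.0–O24.3, in any diagnostic position | 2000-07-01 – 2009-12-31 | not linked; no admission in window; self-reported diagnosis year after the year of the last admission; gestational codes only |
| HbA1c claims (MBS) | ≥ `hba1c_min_claims` claims for the HbA1c test item (66551) with service year in the counting window | years 2005–2009 (claims from 2004 are extracted but not counted) | not linked; diagnosis year after the window end |
| Dispensing (PBS) | ≥ 1 claim for insulin or an OHA in the look-back window | 365 days before recruitment | not linked; no dispensing claim of any kind in the look-back (no observable dispensing history); veterans'-affairs card (their medications bypass the claims collection) |

ICD matching is by code prefix with dots retained ("E11" matches
"E11.9"), following the ICD-10-AM hierarchy. The self-reported
diagnosis year is `year_of_birth + age_at_diagnosis`; both fields are
year-valued, so the comparison carries an inherent ±1-year uncertainty
and is made at year resolution.

The hospital-record diabetes type pools codes across all admissions
with precedence E10 > E11 > (E13, O24.0–O24.3) > E14. A single type per
participant is wanted and the sources give no tie-break, so the
precedence runs from the most specific aetiology downwards;
participants with both E10 and E11 codes are counted as conflicts.
Which codes constitute "gestational only" is likewise not pinned down
by the sources; the default treats any O24-prefixed code as
gestational, and the set is configurable.

## Agreement statistics

With self-report as rows and the criterion as columns,

- sensitivity = tp/(tp+fn), specificity = tn/(fp+tn),
- PPV = tp/(tp+fp), NPV = tn/(fn+tn),
- kappa = (p_o − p_e)/(1 − p_e), with p_o the observed agreement and
  p_e the chance agreement from the marginals.

The kappa is the two-rater case of the Fleiss formulation, which
coincides with Cohen's kappa; no continuity correction is applied.
Uncertain-status participants never enter the 2×2 — they are tabulated
separately, as a fifth row of each report block. A statistic whose
denominator is zero is reported as undefined (`NA`), never as 0.
Reports print percentages to one decimal and kappa to two, matching
the conventional precision for these tables; machine-readable output
keeps full precision. Cell counts are held as doubles internally:
marginal products overflow 32-bit integers already at cohort sizes in
the hundreds of thousands.

```{r}
agreement_stats(confusion_table(15143, 3943, 2904, 169983, 557, 596))
```

## The synthetic cohort generator

`simulate_cohort()` emulates the confusion structure of a linked
validation study: true status (and type) per participant, then
conditionally independent questionnaire responses, admissions with
coded diagnoses, HbA1c claim counts, dispensing claims and linkage
flags. It exists so that every pipeline stage has an executable oracle;
it does not attempt to reproduce any real cohort's demographic
structure or exclusion counts.

Default parameters are fixed at values a linkage validation study of
older Australians would find realistic: prevalence 9.05%, type 1
fraction 3.7% of diabetics, 72% admitted over the decade, hospital
coding sensitivity 0.84 and specificity 0.978, 71.4% of diabetics with
a dispensing claim in the look-back year, 58% reporting OHAs, 2.4%
veterans'-affairs card holders, 99.5% linkage. HbA1c rates (0.45/year
for diabetics, 0.01 otherwise) reflect that the test is a periodic
monitoring test for diabetics and an occasional screening test
otherwise.

Design choices worth knowing:

- **Counter-based randomness.** Every draw is a pure function of
  (seed, field, participant index) via a splitmix64 hash (in C++), so a
  run is reproducible byte-for-byte and enlarging the cohort leaves
  earlier participants bit-identical — R's sequential RNG cannot offer
  that. Poisson counts are drawn by quantile inversion of a single
  uniform; event dates are uniform within their windows.
- **Closed forms by construction.** The generator keeps administrative
  outcomes and subset inclusion independent of the questionnaire
  response given true status. `expected_stats()` then computes expected
  cell masses by the law of total probability, and pipeline estimates
  on generated cohorts are tested against them within three binomial
  standard errors. Three consequences of this design: admitted
  participants always have one admission on or after recruitment (so
  the diagnosed-after-last-admission exclusion cannot fire on generated
  data), no O24 codes are emitted (so the gestational-only exclusion
  cannot fire), and the 2005–09 HbA1c count is drawn directly as
  Poisson(5 × annual rate) rather than by thinning a 2004–09 stream
  (leap days would make date-thinning inexact). All three rules are
  still implemented and are exercised by hand-built fixtures in the
  unit tests.
- **Free text is sampled verbatim from the lexicons**, plus unrelated
  decoy illnesses ("arthritis", "asthma", ...), so the matcher is
  exercised without fuzzy logic.

What passing tests on generated data do **not** show: robustness to
misspelled free text, to coding-practice drift over calendar time, to
admission- or claim-rate dependence on disease severity, or to
linkage error correlated with health status. Real cohorts have all
four; the generator has none, by design, because each would break the
closed-form oracle that makes the pipeline verifiable.

## Problem sizes and numerical checks

The test suite generates cohorts between 300 and 30,000 participants
for unit and property tests; the end-to-end recovery check and the
acceptance script use 100,000 participants, which runs the generator
plus full pipeline in a few seconds. Agreement statistics are checked
against an independent individual-level recount on 1,000 random tables
to 10⁻¹², kappa against an independent library implementation, and the
hospital-type precedence by exhaustive enumeration over all 64 subsets
of a representative code pool.

## Known limitations

- Lexicon matching is exact (after normalisation); coverage is bounded
  by the packaged term lists.
- Record linkage itself is out of scope: linkage status enters as a
  boolean flag per source.
- The uncertain group overlaps two paths (uncertain free text and
  OHA-only medication) whose union, not their separate real-world
  sizes, is what the algorithm can report.
- Typing from questionnaire data is known to agree poorly with
  hospital-recorded type for type 1; the package reports the
  cross-tabulation rather than attempting clinical adjudication, and
  hospital codes are used only as a comparison standard, never as a
  typing input.
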