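#' Registry phenotyping rules for thyroid neoplasia
#'
#' These functions turn per-participant registry and questionnaire records
#' into auditable case/control/excluded assignments for the two outcomes:
#' differentiated thyroid cancer (ICD-10 C73, restricted to papillary and
#' follicular histology) and benign nodular thyroid disease (ICD-10 D34,
#' toxic nodules excluded). Each outcome gets its own control group:
#' cancer controls have no history of any cancer (any C-prefixed code);
#' benign controls have no D34 record of any kind. Every participant ends
#' up in exactly one of case / control / excluded per outcome, and every
#' exclusion carries a reason.
#'
#' @name cohort_rules
NULL

EXCLUDED_HISTOLOGY <- c("medullary", "anaplastic", "lymphoma", "unspecified")
HISTOLOGY_CLASSES <- c("papillary", "follicular", EXCLUDED_HISTOLOGY,
                       "not_applicable")

validate_diagnoses <- function(diagnoses) {
  needed <- c("participant_id", "icd10_code", "diagnosis_date",
              "histology_class", "toxic_flag")
  assert_that(all(needed %in% names(diagnoses)),
              "diagnosis table lacks columns: %s",
              paste(setdiff(needed, names(diagnoses)), collapse = ", "))
  bad <- !grepl("^[A-Z][0-9]{2}", diagnoses$icd10_code)
  if (any(bad)) {
    stopf("malformed ICD-10 code(s) in record(s): %s",
          paste(sprintf("%s[%s]", diagnoses$participant_id[bad],
                        diagnoses$icd10_code[bad]), collapse = ", "))
  }
  bad_h <- !diagnoses$histology_class %in% HISTOLOGY_CLASSES
  if (any(bad_h)) {
    stopf("unknown histology class(es): %s",
          paste(unique(diagnoses$histology_class[bad_h]), collapse = ", "))
  }
  diagnoses$diagnosis_date <- as.Date(diagnoses$diagnosis_date)
  diagnoses
}

empty_assignment <- function(ids, outcome) {
  data.frame(participant_id = ids, outcome = outcome,
             status = "control", exclusion_reason = "",
             index_date = as.Date(NA), stringsAsFactors = FALSE)
}

#' Define differentiated thyroid cancer cases
#'
#' Cases hold at least one C73 registry record with papillary or
#' follicular histology; the earliest such date is the index date, so
#' duplicated records and recurrences collapse to one case. Any C73
#' record with medullary, anaplastic, lymphoma, or unspecified histology
#' excludes the participant outright (reason `"histology"`), regardless
#' of other eligible records, reflecting the different etiology of those
#' subtypes.
#'
#' @param participants Participant table (needs `participant_id`).
#' @param diagnoses Diagnosis table: `participant_id`, `icd10_code`,
#'   `diagnosis_date`, `histology_class`, `toxic_flag`.
#' @return Assignment table: `participant_id`, `outcome = "cancer"`,
#'   `status` in case/control/excluded, `exclusion_reason`, `index_date`.
#'   Non-case rows come back as provisional controls; control eligibility
#'   is finalized by [select_controls()].
#' @export
define_thyroid_cancer_cases <- function(participants, diagnoses) {
  diagnoses <- validate_diagnoses(diagnoses)
  out <- empty_assignment(participants$participant_id, "cancer")
  c73 <- diagnoses[startsWith(diagnoses$icd10_code, "C73"), , drop = FALSE]
  if (nrow(c73)) {
    bad_ids <- unique(c73$participant_id[c73$histology_class %in%
                                           EXCLUDED_HISTOLOGY])
    ok <- c73[c73$histology_class %in% c("papillary", "follicular") &
                !c73$participant_id %in% bad_ids, , drop = FALSE]
    if (nrow(ok)) {
      first <- stats::aggregate(diagnosis_date ~ participant_id, ok, min)
      i <- match(first$participant_id, out$participant_id)
      out$status[i] <- "case"
      out$index_date[i] <- first$diagnosis_date
    }
    j <- match(intersect(bad_ids, out$participant_id), out$participant_id)
    out$status[j] <- "excluded"
    out$exclusion_reason[j] <- "histology"
  }
  out
}

#' Define benign nodular thyroid disease cases
#'
#' Cases hold at least one non-toxic D34 record; the earliest non-toxic
#' date is the index. Any toxic D34 record excludes the participant
#' (reason `"toxic"`).
#'
#' @inheritParams define_thyroid_cancer_cases
#' @return Assignment table with `outcome = "benign"`.
#' @export
define_benign_cases <- function(participants, diagnoses) {
  diagnoses <- validate_diagnoses(diagnoses)
  out <- empty_assignment(participants$participant_id, "benign")
  d34 <- diagnoses[startsWith(diagnoses$icd10_code, "D34"), , drop = FALSE]
  if (nrow(d34)) {
    toxic_ids <- unique(d34$participant_id[d34$toxic_flag])
    ok <- d34[!d34$toxic_flag & !d34$participant_id %in% toxic_ids, ,
              drop = FALSE]
    if (nrow(ok)) {
      first <- stats::aggregate(diagnosis_date ~ participant_id, ok, min)
      i <- match(first$participant_id, out$participant_id)
      out$status[i] <- "case"
      out$index_date[i] <- first$diagnosis_date
    }
    j <- match(intersect(toxic_ids, out$participant_id), out$participant_id)
    out$status[j] <- "excluded"
    out$exclusion_reason[j] <- "toxic"
  }
  out
}

#' Exclude diagnostically uncertain dual diagnoses
#'
#' Participants whose thyroid-cancer and benign-nodule index dates fall
#' strictly within `window_months` of each other are removed from both
#' analyses (reason `"diagnostic_uncertainty"`): a nodule worked up and
#' found malignant within a year is one clinical episode, not two
#' outcomes. Pairs at least the window apart keep both statuses — a
#' remote benign-nodule history before cancer is real and expected.
#' Months are converted to days as `365.25 / 12` per month; a gap exactly
#' at the boundary is retained.
#'
#' @param cancer_assign,benign_assign Outputs of the two case definitions.
#' @param window_months Width of the exclusion window; `0` disables it.
#' @return `list(cancer = ..., benign = ...)`, both tables updated.
#' @export
apply_dual_diagnosis_exclusion <- function(cancer_assign, benign_assign,
                                           window_months = 12) {
  assert_that(is.numeric(window_months) && window_months >= 0,
              "window_months must be >= 0")
  window_days <- window_months * 365.25 / 12
  both <- merge(
    cancer_assign[cancer_assign$status == "case",
                  c("participant_id", "index_date")],
    benign_assign[benign_assign$status == "case",
                  c("participant_id", "index_date")],
    by = "participant_id", suffixes = c("_cancer", "_benign")
  )
  gap <- abs(as.numeric(both$index_date_cancer - both$index_date_benign))
  drop_ids <- both$participant_id[gap < window_days]
  for (nm in c("cancer", "benign")) {
    tab <- if (nm == "cancer") cancer_assign else benign_assign
    i <- match(intersect(drop_ids, tab$participant_id), tab$participant_id)
    tab$status[i] <- "excluded"
    tab$exclusion_reason[i] <- "diagnostic_uncertainty"
    tab$index_date[i] <- as.Date(NA)
    if (nm == "cancer") cancer_assign <- tab else benign_assign <- tab
  }
  list(cancer = cancer_assign, benign = benign_assign)
}

#' Type 2 diabetes status from baseline self-report
#'
#' A participant counts as having type 2 diabetes iff they self-report a
#' doctor's diabetes diagnosis, were 35 or older at diagnosis, did not
#' start insulin within the first year, and were diagnosed at least one
#' year before enrollment — the latter three rules screen out probable
#' type 1 diabetes. Missing subfields fail the criterion (conservative:
#' no imputation).
#'
#' @param participants Table with `self_report_diabetes`,
#'   `age_at_diabetes_diagnosis`, `insulin_within_first_year`,
#'   `years_since_diabetes_diagnosis`.
#' @return Data frame `participant_id`, `t2dm` (logical).
#' @export
define_t2dm_status <- function(participants) {
  yes <- function(x) !is.na(x) & x
  t2dm <- yes(participants$self_report_diabetes) &
    (!is.na(participants$age_at_diabetes_diagnosis) &
       participants$age_at_diabetes_diagnosis >= 35) &
    (!is.na(participants$insulin_within_first_year) &
       !participants$insulin_within_first_year) &
    (!is.na(participants$years_since_diabetes_diagnosis) &
       participants$years_since_diabetes_diagnosis >= 1)
  data.frame(participant_id = participants$participant_id, t2dm = t2dm,
             stringsAsFactors = FALSE)
}

#' Finalize outcome-specific control groups
#'
#' Applies the control-eligibility rules to the provisional controls of a
#' case assignment: for the cancer analysis, any participant with any
#' C-prefixed diagnosis (any cancer history) is excluded from the control
#' pool (reason `"cancer_history"`); for the benign analysis, any D34
#' record — toxic or not — excludes (reason `"nodule_history"`). Cases
#' and prior exclusions are untouched.
#'
#' @param assignment An assignment table from a case definition.
#' @param diagnoses Diagnosis table.
#' @return The updated assignment table.
#' @export
select_controls <- function(assignment, diagnoses) {
  diagnoses <- validate_diagnoses(diagnoses)
  outcome <- assignment$outcome[1]
  if (outcome == "cancer") {
    bad <- unique(diagnoses$participant_id[grepl("^C",
                                                 diagnoses$icd10_code)])
    reason <- "cancer_history"
  } else {
    bad <- unique(diagnoses$participant_id[startsWith(diagnoses$icd10_code,
                                                      "D34")])
    reason <- "nodule_history"
  }
  i <- which(assignment$status == "control" &
               assignment$participant_id %in% bad)
  assignment$status[i] <- "excluded"
  assignment$exclusion_reason[i] <- reason
  assignment
}

#' Sensitivity exclusion of thyroid dysfunction
#'
#' Removes participants carrying any diagnosis whose code starts with a
#' prefix in `code_list` (default hypothyroidism E03 and hyperthyroidism
#' E05) from cases and controls alike, for sensitivity re-analysis.
#'
#' @param assignment An assignment table.
#' @param diagnoses Diagnosis table.
#' @param code_list Character vector of ICD-10 code prefixes.
#' @return The updated assignment; attribute `n_removed` records the count.
#' @export
sensitivity_exclude_thyroid_dysfunction <- function(assignment, diagnoses,
                                                    code_list = c("E03",
                                                                  "E05")) {
  if (length(code_list) == 0) {
    warning("empty thyroid-dysfunction code list: no-op")
    attr(assignment, "n_removed") <- 0L
    return(assignment)
  }
  diagnoses <- validate_diagnoses(diagnoses)
  pat <- paste0("^(", paste(code_list, collapse = "|"), ")")
  flagged <- unique(diagnoses$participant_id[grepl(pat,
                                                   diagnoses$icd10_code)])
  i <- which(assignment$status %in% c("case", "control") &
               assignment$participant_id %in% flagged)
  assignment$status[i] <- "excluded"
  assignment$exclusion_reason[i] <- "thyroid_dysfunction"
  attr(assignment, "n_removed") <- length(i)
  assignment
}

#' Build both outcome cohorts in one pass
#'
#' Runs case definitions, the dual-diagnosis window, and control
#' selection for both outcomes, and attaches type 2 diabetes status.
#'
#' @inheritParams define_thyroid_cancer_cases
#' @param window_months Dual-diagnosis exclusion window.
#' @return List with `cancer` and `benign` assignment tables, `t2dm`
#'   status table, and a `log` data.frame of counts at each filter step.
#' @export
build_cohort_assignments <- function(participants, diagnoses,
                                     window_months = 12) {
  ca <- define_thyroid_cancer_cases(participants, diagnoses)
  ba <- define_benign_cases(participants, diagnoses)
  dd <- apply_dual_diagnosis_exclusion(ca, ba, window_months)
  ca <- select_controls(dd$cancer, diagnoses)
  ba <- select_controls(dd$benign, diagnoses)
  counts <- function(a) table(factor(a$status,
                                     c("case", "control", "excluded")))
  log <- data.frame(outcome = c("cancer", "benign"),
                    n_case = c(counts(ca)[["case"]], counts(ba)[["case"]]),
                    n_control = c(counts(ca)[["control"]],
                                  counts(ba)[["control"]]),
                    n_excluded = c(counts(ca)[["excluded"]],
                                   counts(ba)[["excluded"]]))
  list(cancer = ca, benign = ba,
       t2dm = define_t2dm_status(participants), log = log)
}
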