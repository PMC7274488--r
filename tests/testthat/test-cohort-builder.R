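fx <- load_phenotyping_fixture()

test_that("every participant is exactly one of case/control/excluded", {
  asn <- build_cohort_assignments(fx$participants, fx$diagnoses)
  for (tab in list(asn$cancer, asn$benign)) {
    expect_setequal(tab$participant_id, fx$participants$participant_id)
    expect_false(anyDuplicated(tab$participant_id) > 0)
    expect_true(all(tab$status %in% c("case", "control", "excluded")))
    excl <- tab$status == "excluded"
    expect_true(all(nzchar(tab$exclusion_reason[excl])))
    expect_true(all(!nzchar(tab$exclusion_reason[!excl])))
  }
})

test_that("control eligibility follows the closure rules", {
  asn <- build_cohort_assignments(fx$participants, fx$diagnoses)
  # unrelated cancer: out of the cancer control pool, fine as benign control
  expect_equal(status_of(asn$cancer, "p09"), "excluded")
  expect_equal(reason_of(asn$cancer, "p09"), "cancer_history")
  expect_equal(status_of(asn$benign, "p09"), "control")
  # no diagnoses at all: control in both
  expect_equal(status_of(asn$cancer, "p06"), "control")
  expect_equal(status_of(asn$benign, "p06"), "control")
  # toxic nodule: neither benign case nor benign control
  expect_equal(status_of(asn$benign, "p05"), "excluded")
  # thyroid cancer cases are not eligible benign controls (D34-free ones stay controls)
  expect_equal(status_of(asn$benign, "p01"), "control")
})

test_that("widening the dual-diagnosis window never increases case counts", {
  ca <- define_thyroid_cancer_cases(fx$participants, fx$diagnoses)
  ba <- define_benign_cases(fx$participants, fx$diagnoses)
  n_cases <- vapply(c(0, 6, 12, 24, 48), function(w) {
    dd <- apply_dual_diagnosis_exclusion(ca, ba, w)
    sum(dd$cancer$status == "case") + sum(dd$benign$status == "case")
  }, numeric(1))
  expect_true(all(diff(n_cases) <= 0))
  # degenerate window excludes nobody
  dd0 <- apply_dual_diagnosis_exclusion(ca, ba, 0)
  expect_identical(dd0$cancer, ca)
  expect_identical(dd0$benign, ba)
})

test_that("assignments are idempotent", {
  a1 <- build_cohort_assignments(fx$participants, fx$diagnoses)
  a2 <- build_cohort_assignments(fx$participants, fx$diagnoses)
  expect_identical(a1$cancer, a2$cancer)
  expect_identical(a1$benign, a2$benign)
  expect_identical(a1$t2dm, a2$t2dm)
})

test_that("malformed ICD-10 codes fail naming the record", {
  bad <- fx$diagnoses
  bad$icd10_code[3] <- "73C"
  expect_error(define_thyroid_cancer_cases(fx$participants, bad),
               "p03.*73C")
})

test_that("sensitivity exclusion removes dysfunction codes and handles edge cases", {
  asn <- build_cohort_assignments(fx$participants, fx$diagnoses)
  out <- sensitivity_exclude_thyroid_dysfunction(asn$cancer, fx$diagnoses)
  expect_equal(status_of(out, "p10"), "excluded")
  expect_equal(reason_of(out, "p10"), "thyroid_dysfunction")
  expect_equal(attr(out, "n_removed"), 1L)

  expect_warning(
    noop <- sensitivity_exclude_thyroid_dysfunction(asn$cancer, fx$diagnoses,
                                                    code_list = character()),
    "no-op")
  expect_identical(noop$status, asn$cancer$status)

  # flagging everyone empties the cohort; downstream analyses then refuse
  all_codes <- unique(substr(fx$diagnoses$icd10_code, 1, 1))
  every <- sensitivity_exclude_thyroid_dysfunction(
    asn$cancer, fx$diagnoses, code_list = c(all_codes, "")
  )
  expect_true(all(every$status == "excluded" |
                    !every$participant_id %in% fx$diagnoses$participant_id))
})

test_that("the rules partition a large simulated cohort too", {
  ch <- simulate_cohort(sim_config(n_participants = 15000,
                                   outcome_baseline_prevalence = 0.01,
                                   outcome = "benign", seed = 77))
  asn <- build_cohort_assignments(ch$participants, ch$diagnoses)
  expect_equal(sum(asn$log[asn$log$outcome == "benign",
                           c("n_case", "n_control", "n_excluded")]),
               15000)
  # simulated benign cases survive phenotyping unless toxic/dual flagged
  expect_gt(asn$log$n_case[asn$log$outcome == "benign"], 0)
})
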