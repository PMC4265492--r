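test_that("a record satisfying every criterion is eligible", {
  dec <- evaluateEligibility(eligibleRecord())
  expect_true(isEligible(dec))
  expect_length(failedCriteria(dec), 0)
  expect_equal(nrow(criteriaTable(dec)), 27)
})

test_that("single violations fail exactly their criterion", {
  bmiDec <- evaluateEligibility(eligibleRecord(bmi = 33))
  expect_false(isEligible(bmiDec))
  expect_identical(failedCriteria(bmiDec), "exc_bmi")

  tarDec <- evaluateEligibility(eligibleRecord(lower_lobe_tar = 10.5))
  expect_false(isEligible(tarDec))
  expect_identical(failedCriteria(tarDec), "exc_lower_lobe_tar")
})

test_that("boundary values follow the printed comparison directions", {
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(fev1_pct_pred = 20))))     # 20% is inside 20-45%
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(fev1_pct_pred = 45))))
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(dlco_pct_pred = 20))))     # exclusion is < 20
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(bmi = 32))))               # exclusion is > 32
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(bmi = 18))))
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(paco2 = 50))))             # inclusion is <= 50
  expect_false(isEligible(evaluateEligibility(
    eligibleRecord(rv_pct_pred = 150))))      # inclusion is > 150
  expect_false(isEligible(evaluateEligibility(
    eligibleRecord(six_mwd = 140))))          # > 140 m required
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(lower_lobe_tar = 11))))    # exclusion is < 11
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(prednisolone_daily_mg = 5))))
  expect_true(isEligible(evaluateEligibility(
    eligibleRecord(largest_bulla_fraction_of_lobe = 1 / 3))))
})

test_that("the dyspnea threshold convention is switchable and surfaced", {
  rec <- eligibleRecord(mmrc = 2)
  geq <- evaluateEligibility(rec, mmrc_rule = "geq2")
  gt <- evaluateEligibility(rec, mmrc_rule = "gt2")
  expect_true(isEligible(geq))
  expect_false(isEligible(gt))
  expect_identical(failedCriteria(gt), "inc_mmrc")
  expect_equal(geq@metadata$mmrc_rule, "geq2")
  expect_equal(gt@metadata$mmrc_rule, "gt2")
})

test_that("catheter PAP is definitive over echo; missing PAP needs attestation", {
  echoHigh <- eligibleRecord(pap_systolic_echo = 50)
  expect_false(isEligible(evaluateEligibility(echoHigh)))
  overridden <- eligibleRecord(pap_systolic_echo = 50,
                               pap_systolic_rhc = 40)
  expect_true(isEligible(evaluateEligibility(overridden)))
  rhcMeanHigh <- eligibleRecord(pap_mean_echo = 30, pap_mean_rhc = 36)
  expect_false(isEligible(evaluateEligibility(rhcMeanHigh)))
  noPap <- eligibleRecord(
    attestations = c(no_pulmonary_hypertension_history = FALSE))
  expect_false(isEligible(evaluateEligibility(noPap)))
  expect_identical(failedCriteria(evaluateEligibility(noPap)), "exc_pap")
})

test_that("worsening one numeric field through its threshold flips only that criterion", {
  flips <- list(
    list(field = "tlc_pct_pred", bad = 99, id = "inc_tlc"),
    list(field = "rv_pct_pred", bad = 150, id = "inc_rv"),
    list(field = "paco2", bad = 51, id = "inc_paco2"),
    list(field = "pao2", bad = 50, id = "inc_pao2"),
    list(field = "dlco_pct_pred", bad = 19.9, id = "exc_dlco"),
    list(field = "bmi", bad = 32.1, id = "exc_bmi"),
    list(field = "prednisolone_daily_mg", bad = 5.1, id = "exc_steroids"),
    list(field = "largest_bulla_fraction_of_lobe", bad = 0.4,
         id = "exc_bulla"),
    list(field = "copd_hospitalizations", bad = 4, id = "exc_exacerbation"),
    list(field = "age", bad = 76, id = "inc_age"))
  base <- criteriaTable(evaluateEligibility(eligibleRecord()))
  for (f in flips) {
    args <- setNames(list(f$bad), f$field)
    dec <- evaluateEligibility(do.call(eligibleRecord, args))
    expect_identical(failedCriteria(dec), f$id, label = f$field)
    expect_equal(sum(criteriaTable(dec)$pass != base$pass), 1,
                 label = f$field)
  }
  # FEV1 below 20% trips both the inclusion band and the exclusion floor
  dec <- evaluateEligibility(eligibleRecord(fev1_pct_pred = 19))
  expect_setequal(failedCriteria(dec), c("inc_fev1", "exc_fev1_low"))
})

test_that("the decision is a pure conjunction of the criteria", {
  dec <- evaluateEligibility(eligibleRecord(
    bmi = 40, lower_lobe_tar = 9,
    attestations = c(no_bronchiectasis = FALSE)))
  expect_false(isEligible(dec))
  expect_setequal(failedCriteria(dec),
                  c("exc_bmi", "exc_lower_lobe_tar", "exc_bronchiectasis"))
  expect_identical(isEligible(dec), all(criteriaTable(dec)$pass))
})

test_that("record validation rejects malformed inputs", {
  expect_error(patientRecord(age = 60, fev1_pct_pred = 35,
                             tlc_pct_pred = 105, rv_pct_pred = 180,
                             six_mwd = 250, mmrc = 7, paco2 = 45,
                             pao2 = 60, bmi = 25, dlco_pct_pred = 35,
                             lower_lobe_tar = 13), "mmrc")
  expect_error(eligibleRecord(attestations = c(not_a_thing = TRUE)),
               "unknown attestation")
  expect_error(eligibleRecord(bmi = NA_real_), "non-finite")
})

test_that("patient records parse from JSON", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    age = 60, fev1_pct_pred = 35, tlc_pct_pred = 105, rv_pct_pred = 180,
    six_mwd = 250, mmrc = 3, paco2 = 45, pao2 = 60, bmi = 33,
    dlco_pct_pred = 35, lower_lobe_tar = list(left = 13, right = 14),
    attestations = list(no_bronchiectasis = TRUE)),
    path, auto_unbox = TRUE)
  dec <- evaluateEligibility(readPatientRecord(path))
  expect_identical(failedCriteria(dec), "exc_bmi")
})
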