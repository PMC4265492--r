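.REQUIRED_MEASUREMENTS <- c(
  "age", "fev1_pct_pred", "tlc_pct_pred", "rv_pct_pred", "six_mwd", "mmrc",
  "paco2", "pao2", "bmi", "dlco_pct_pred", "lower_lobe_tar_left",
  "lower_lobe_tar_right", "prednisolone_daily_mg",
  "largest_bulla_fraction_of_lobe", "copd_hospitalizations")

.OPTIONAL_MEASUREMENTS <- c("pap_systolic_echo", "pap_mean_echo",
                            "pap_systolic_rhc", "pap_mean_rhc")

.REQUIRED_ATTESTATIONS <- c(
  "heterogeneous_ulpe", "non_smoking_6mo", "optimized_medical_management",
  "rehabilitation_completed", "consent_capable", "no_interfering_condition",
  "no_bronchiectasis", "no_pneumothorax_effusion_6mo",
  "no_excluded_cardiac_surgical_history", "no_recent_exacerbation_6wk",
  "no_coagulopathy_anticoagulants", "no_pulmonary_hypertension_history")

#' Construct a validated PatientRecord
#'
#' Pulmonary-artery pressures are optional and may come from
#' echocardiography and/or right-heart catheter; catheter values are
#' definitive when both are present. Attestations default to TRUE
#' (condition satisfied / excluding history absent) so that a record can be
#' built from the numeric screen alone; set them explicitly for real use.
#'
#' @param age years.
#' @param fev1_pct_pred,tlc_pct_pred,rv_pct_pred,dlco_pct_pred percent of
#'   predicted.
#' @param six_mwd post-rehabilitation six-minute walk distance, meters.
#' @param mmrc modified Medical Research Council dyspnea score, integer 0-4.
#' @param paco2,pao2 arterial blood gases on room air, mm Hg.
#' @param bmi body mass index, kg/m^2.
#' @param lower_lobe_tar lower-lobe TAR percent; a single value or
#'   \code{c(left =, right =)} — the minimum of the two sides is screened.
#' @param prednisolone_daily_mg daily systemic steroid dose, mg.
#' @param largest_bulla_fraction_of_lobe largest upper-lobe bulla as a
#'   fraction of its lobe's volume, in [0, 1].
#' @param copd_hospitalizations COPD-related hospitalizations requiring
#'   antibiotics in the past 12 months.
#' @param pap_systolic_echo,pap_mean_echo,pap_systolic_rhc,pap_mean_rhc
#'   pulmonary-artery pressures, mm Hg; NA when not measured.
#' @param attestations named logical vector overriding any of the history
#'   attestations (see \code{stepup:::.REQUIRED_ATTESTATIONS}).
#' @return a \linkS4class{PatientRecord}.
#' @examples
#' rec <- patientRecord(age = 60, fev1_pct_pred = 35, tlc_pct_pred = 105,
#'                      rv_pct_pred = 180, six_mwd = 250, mmrc = 3,
#'                      paco2 = 45, pao2 = 60, bmi = 25,
#'                      dlco_pct_pred = 35, lower_lobe_tar = 13)
#' isEligible(evaluateEligibility(rec))
#' @export
patientRecord <- function(age, fev1_pct_pred, tlc_pct_pred, rv_pct_pred,
                          six_mwd, mmrc, paco2, pao2, bmi, dlco_pct_pred,
                          lower_lobe_tar, prednisolone_daily_mg = 0,
                          largest_bulla_fraction_of_lobe = 0,
                          copd_hospitalizations = 0,
                          pap_systolic_echo = NA_real_,
                          pap_mean_echo = NA_real_,
                          pap_systolic_rhc = NA_real_,
                          pap_mean_rhc = NA_real_,
                          attestations = logical()) {
  if (length(lower_lobe_tar) == 1L && is.null(names(lower_lobe_tar)))
    lower_lobe_tar <- c(left = lower_lobe_tar, right = lower_lobe_tar)
  if (!all(c("left", "right") %in% names(lower_lobe_tar)))
    stop("lower_lobe_tar must be a single value or c(left=, right=)",
         call. = FALSE)
  m <- c(age = age, fev1_pct_pred = fev1_pct_pred,
         tlc_pct_pred = tlc_pct_pred, rv_pct_pred = rv_pct_pred,
         six_mwd = six_mwd, mmrc = mmrc, paco2 = paco2, pao2 = pao2,
         bmi = bmi, dlco_pct_pred = dlco_pct_pred,
         lower_lobe_tar_left = unname(lower_lobe_tar["left"]),
         lower_lobe_tar_right = unname(lower_lobe_tar["right"]),
         prednisolone_daily_mg = prednisolone_daily_mg,
         largest_bulla_fraction_of_lobe = largest_bulla_fraction_of_lobe,
         copd_hospitalizations = copd_hospitalizations,
         pap_systolic_echo = pap_systolic_echo,
         pap_mean_echo = pap_mean_echo,
         pap_systolic_rhc = pap_systolic_rhc,
         pap_mean_rhc = pap_mean_rhc)
  att <- setNames(rep(TRUE, length(.REQUIRED_ATTESTATIONS)),
                  .REQUIRED_ATTESTATIONS)
  if (length(attestations)) {
    unknown <- setdiff(names(attestations), .REQUIRED_ATTESTATIONS)
    if (length(unknown))
      stop("unknown attestation(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    att[names(attestations)] <- attestations
  }
  new("PatientRecord", measurements = m, attestations = att)
}

#' Read a patient record from JSON
#'
#' The JSON schema mirrors the \code{\link{patientRecord}} arguments: a flat
#' object of the numeric measurements (with \code{lower_lobe_tar} either a
#' number or an object \code{\{"left":, "right":\}}) plus an optional
#' \code{"attestations"} object of booleans.
#'
#' @param path JSON file path.
#' @return a \linkS4class{PatientRecord}.
#' @export
readPatientRecord <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  llt <- x$lower_lobe_tar
  if (is.list(llt) || !is.null(names(llt))) llt <- unlist(llt)
  args <- x[setdiff(names(x), c("attestations", "lower_lobe_tar"))]
  args$lower_lobe_tar <- llt
  args$attestations <- unlist(x$attestations) %||% logical()
  do.call(patientRecord, args)
}

# effective PAP: right-heart catheter is definitive over echo
.effectivePAP <- function(m, which) {
  rhc <- m[[paste0("pap_", which, "_rhc")]]
  if (is.finite(rhc)) rhc else m[[paste0("pap_", which, "_echo")]]
}

#' Evaluate the inclusion/exclusion screen
#'
#' Applies every computable inclusion and exclusion criterion with the
#' printed comparison direction and inclusive boundary semantics (FEV1 at
#' exactly 20% predicted passes the 20-45% band, DLCO at exactly 20%
#' passes, BMI at exactly 32 passes). Pulmonary-artery pressures missing
#' from both sources are non-excluding only when the absence of pulmonary
#' hypertension is attested. The decision is a pure conjunction: eligible
#' iff no criterion fails.
#'
#' @param record a \linkS4class{PatientRecord}.
#' @param mmrc_rule dyspnea threshold convention: \code{"geq2"} (default;
#'   mMRC >= 2) or \code{"gt2"} (mMRC > 2). The two conventions circulate
#'   for this criterion, so the one applied is echoed in the decision
#'   metadata.
#' @return an \linkS4class{EligibilityDecision}.
#' @export
evaluateEligibility <- function(record, mmrc_rule = c("geq2", "gt2")) {
  stopifnot(is(record, "PatientRecord"))
  mmrc_rule <- match.arg(mmrc_rule)
  m <- as.list(record@measurements)
  a <- as.list(record@attestations)

  rows <- list()
  crit <- function(id, desc, observed, threshold, pass)
    rows[[length(rows) + 1L]] <<- data.frame(
      criterion = id, description = desc,
      observed = as.character(observed), threshold = threshold,
      pass = isTRUE(pass), stringsAsFactors = FALSE)

  crit("inc_age", "Age 40-75 years", m$age, ">=40 & <=75",
       m$age >= 40 && m$age <= 75)
  crit("inc_heterogeneous_ulpe",
       "Heterogeneous emphysema with upper lobe predominance, both lungs",
       a$heterogeneous_ulpe, "attested", a$heterogeneous_ulpe)
  crit("inc_fev1", "FEV1 between 20% and 45% predicted", m$fev1_pct_pred,
       ">=20 & <=45", m$fev1_pct_pred >= 20 && m$fev1_pct_pred <= 45)
  crit("inc_tlc", "TLC >= 100% predicted", m$tlc_pct_pred, ">=100",
       m$tlc_pct_pred >= 100)
  crit("inc_rv", "RV > 150% predicted", m$rv_pct_pred, ">150",
       m$rv_pct_pred > 150)
  crit("inc_6mwd", "Post-rehabilitation 6MWD > 140 m", m$six_mwd, ">140",
       m$six_mwd > 140)
  mmrcPass <- if (mmrc_rule == "geq2") m$mmrc >= 2 else m$mmrc > 2
  crit("inc_mmrc", "Marked dyspnea on the mMRC scale", m$mmrc,
       if (mmrc_rule == "geq2") ">=2" else ">2", mmrcPass)
  crit("inc_paco2", "PaCO2 <= 50 mm Hg", m$paco2, "<=50", m$paco2 <= 50)
  crit("inc_pao2", "PaO2 > 50 mm Hg on room air", m$pao2, ">50",
       m$pao2 > 50)
  crit("inc_nonsmoking", "Non-smoking for 6 months", a$non_smoking_6mo,
       "attested", a$non_smoking_6mo)
  crit("inc_medical_mgmt", "Optimized medical management",
       a$optimized_medical_management, "attested",
       a$optimized_medical_management)
  crit("inc_rehab", "Completed pulmonary rehabilitation",
       a$rehabilitation_completed, "attested", a$rehabilitation_completed)
  crit("inc_consent", "Able to cooperate and consent", a$consent_capable,
       "attested", a$consent_capable)

  crit("exc_interfering", "No condition interfering with follow-up",
       a$no_interfering_condition, "attested", a$no_interfering_condition)
  crit("exc_fev1_low", "FEV1 not < 20% predicted", m$fev1_pct_pred,
       ">=20", m$fev1_pct_pred >= 20)
  crit("exc_dlco", "DLCO not < 20% predicted", m$dlco_pct_pred, ">=20",
       m$dlco_pct_pred >= 20)
  crit("exc_bmi", "BMI not < 18 or > 32 kg/m2", m$bmi, ">=18 & <=32",
       m$bmi >= 18 && m$bmi <= 32)
  papSys <- .effectivePAP(m, "systolic")
  papMean <- .effectivePAP(m, "mean")
  papPass <- if (!is.finite(papSys) && !is.finite(papMean))
    isTRUE(a$no_pulmonary_hypertension_history)
  else !(isTRUE(papSys > 45) || isTRUE(papMean > 35))
  crit("exc_pap",
       "No pulmonary hypertension (systolic PAP <= 45, mean PAP <= 35)",
       sprintf("sys=%s mean=%s", papSys, papMean),
       "sys<=45 & mean<=35 (catheter definitive)", papPass)
  crit("exc_6mwd", "Able to walk > 140 m in 6 minutes", m$six_mwd, ">140",
       m$six_mwd > 140)
  lltMin <- min(m$lower_lobe_tar_left, m$lower_lobe_tar_right)
  crit("exc_lower_lobe_tar",
       "No highly diseased lower lobes (lower-lobe TAR not < 11%)", lltMin,
       ">=11", lltMin >= 11)
  crit("exc_bronchiectasis", "No clinically significant bronchiectasis",
       a$no_bronchiectasis, "attested", a$no_bronchiectasis)
  crit("exc_pneumothorax",
       "No pneumothorax or pleural effusion in previous 6 months",
       a$no_pneumothorax_effusion_6mo, "attested",
       a$no_pneumothorax_effusion_6mo)
  crit("exc_cardiac_history",
       "No excluded cardiac/surgical history",
       a$no_excluded_cardiac_surgical_history, "attested",
       a$no_excluded_cardiac_surgical_history)
  crit("exc_exacerbation",
       "No exacerbation in 6 weeks; <= 3 COPD hospitalizations in 12 months",
       sprintf("attested=%s, hospitalizations=%g",
               a$no_recent_exacerbation_6wk, m$copd_hospitalizations),
       "attested & <=3",
       a$no_recent_exacerbation_6wk && m$copd_hospitalizations <= 3)
  crit("exc_steroids", "No daily systemic steroids > 5 mg prednisolone",
       m$prednisolone_daily_mg, "<=5", m$prednisolone_daily_mg <= 5)
  crit("exc_bulla", "No single bulla > 1/3 of its lobe's volume",
       m$largest_bulla_fraction_of_lobe, "<=1/3",
       m$largest_bulla_fraction_of_lobe <= 1 / 3)
  crit("exc_coagulopathy", "No coagulopathy or anticoagulant use",
       a$no_coagulopathy_anticoagulants, "attested",
       a$no_coagulopathy_anticoagulants)

  criteria <- do.call(rbind, rows)
  new("EligibilityDecision",
      eligible = all(criteria$pass), criteria = criteria,
      failed = criteria$criterion[!criteria$pass],
      metadata = list(mmrc_rule = mmrc_rule,
                      mmrc_rule_note = paste(
                        "two dyspnea threshold conventions circulate",
                        "(mMRC >= 2 vs > 2); applied rule echoed here")))
}

#' @rdname EligibilityDecision-class
#' @export
setMethod("isEligible", "EligibilityDecision", function(x) x@eligible)

#' @rdname EligibilityDecision-class
#' @export
setMethod("criteriaTable", "EligibilityDecision", function(x) x@criteria)

#' @rdname EligibilityDecision-class
#' @export
setMethod("failedCriteria", "EligibilityDecision", function(x) x@failed)

setMethod("show", "EligibilityDecision", function(object) {
  cat("EligibilityDecision:",
      if (object@eligible) "ELIGIBLE" else "NOT ELIGIBLE", "\n")
  cat(sprintf("  %d/%d criteria pass\n", sum(object@criteria$pass),
              nrow(object@criteria)))
  if (length(object@failed))
    cat("  failed:", paste(object@failed, collapse = ", "), "\n")
})
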