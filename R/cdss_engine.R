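# Core decision logic. Stage 1 stratifies the triple-marker result into
# low/high risk of CKD complications; stage 2 emits the individualized
# recommendation set for high-risk patients across five domains:
# cardiovascular risk reduction, potassium management, proteinuria
# management, nephrology referral, and patient education. Low-risk patients
# get exactly one action: repeat triple-marker testing in 6 months.
#
# Every comparator lives in one thresholds object so the dialect is visible
# and testable. The printed rules use strict inequalities (eGFR_Cys < 60,
# ACR > 30, K > 5.5, SBP > 150, KFRE > 3%); boundary values such as
# eGFR_Cys = 60 or ACR = 30 fall in neither printed clause and are assigned
# LOW by convention here.

ANTIHYPERTENSIVE_CLASSES <- c("acei_arb", "thiazide_diuretic", "loop_diuretic",
                              "beta_blocker", "ccb", "other_antihypertensive")
DIURETIC_CLASSES <- c("thiazide_diuretic", "loop_diuretic")

EDUCATION_ITEMS <- c("education_ckd_general", "education_nsaid_avoidance",
                     "education_diet")

#' Decision-support thresholds
#'
#' Central comparator configuration for the rules engine. All comparisons on
#' `egfr_cys_high`, `acr_high`, `k_referral`, `sbp_referral`, `kfre_referral`
#' and `egfr_cys_referral` are strict; `k_diet_low` opens the half-open
#' potassium counseling band `(k_diet_low, k_referral]`.
#'
#' @param egfr_cys_high eGFR_Cys below which a patient is high risk (60).
#' @param acr_high ACR above which a patient is high risk (30 mg/g).
#' @param egfr_cys_referral eGFR_Cys referral cutoff (30).
#' @param k_referral Potassium referral cutoff (5.5 mEq/L).
#' @param acr_referral ACR referral cutoff (300 mg/g).
#' @param sbp_referral Systolic BP referral cutoff (150 mmHg), applied only
#'   with >= `n_agents_referral` antihypertensive classes including a diuretic.
#' @param n_agents_referral Minimum antihypertensive class count (3).
#' @param kfre_referral 5-year kidney-failure risk cutoff (0.03).
#' @param k_diet_low Lower edge of the potassium diet-counseling band (5.0).
#' @param statin_age Minimum age for the statin recommendation (50).
#' @return A list of class `cdss_thresholds`.
#' @export
cdss_thresholds <- function(egfr_cys_high = 60, acr_high = 30,
                            egfr_cys_referral = 30, k_referral = 5.5,
                            acr_referral = 300, sbp_referral = 150,
                            n_agents_referral = 3, kfre_referral = 0.03,
                            k_diet_low = 5.0, statin_age = 50) {
  structure(as.list(environment()), class = "cdss_thresholds")
}

#' Triple-marker risk stratification
#'
#' High risk iff eGFR_Cys < 60 mL/min/1.73m^2 and/or ACR > 30 mg/g;
#' otherwise low risk. Vectorized; exact boundary values are low.
#'
#' @param egfr_cys Cystatin-C eGFR, mL/min/1.73m^2 (> 0).
#' @param acr Urine ACR, mg/g (> 0).
#' @param thresholds A [cdss_thresholds()].
#' @return `"low"` or `"high"` per element.
#' @export
stratify_risk <- function(egfr_cys, acr, thresholds = cdss_thresholds()) {
  check_that(all(is.finite(egfr_cys) & egfr_cys > 0), "egfr_cys",
             "must be positive")
  check_that(all(is.finite(acr) & acr > 0), "acr", "must be positive")
  ifelse(egfr_cys < thresholds$egfr_cys_high | acr > thresholds$acr_high,
         "high", "low")
}

#' Assemble a patient state for the rules engine
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param panel A [triple_marker_panel()] (or list with `egfr_cys`, `acr`).
#' @param potassium Most recent potassium, mEq/L, or `NA` when never
#'   measured (the potassium rules are then unassessed).
#' @param recent_sbp Most recent systolic BP, mmHg.
#' @param active_med_classes Character vector of active medication classes.
#' @param preferred_language Language for education materials.
#' @param kfre Optional precomputed 5-year kidney-failure risk; when `NULL`
#'   it is derived via [kfre_5yr()] from age, sex, eGFR_Cys and ACR.
#' @return A list of class `patient_state`. `n_antihypertensive_classes` and
#'   `has_diuretic` are derived from `active_med_classes`, so they cannot
#'   disagree with it.
#' @export
patient_state <- function(age, sex, panel, potassium = NA_real_,
                          recent_sbp = NA_real_, active_med_classes = character(),
                          preferred_language = "English", kfre = NULL) {
  sex <- match_sex(sex)
  if (is.null(kfre)) {
    kfre <- kfre_5yr(age, sex, panel$egfr_cys, panel$acr)
  }
  structure(list(
    age = age, sex = sex, panel = panel, potassium = potassium,
    recent_sbp = recent_sbp,
    active_med_classes = unique(active_med_classes),
    n_antihypertensive_classes =
      length(intersect(unique(active_med_classes), ANTIHYPERTENSIVE_CLASSES)),
    has_diuretic = any(active_med_classes %in% DIURETIC_CLASSES),
    preferred_language = preferred_language,
    kfre_5yr = kfre
  ), class = "patient_state")
}

#' Nephrology referral criteria
#'
#' Evaluates the highest-risk criteria: confirmed eGFR_Cys < 30
#' mL/min/1.73m^2; potassium > 5.5 mEq/L; ACR > 300 mg/g; SBP > 150 mmHg
#' despite 3 or more antihypertensive agents including a diuretic; or > 3%
#' 5-year kidney-failure risk. All comparisons strict as printed. A missing
#' potassium leaves that criterion unmet and records it as unassessed.
#'
#' @param state A [patient_state()].
#' @param thresholds A [cdss_thresholds()].
#' @return Character vector of met criteria, a subset of
#'   `c("egfr_cys_lt30", "k_gt_5_5", "acr_gt_300",
#'   "sbp_gt150_on_3agents_with_diuretic", "kfre_gt_3pct")`, with an
#'   `unassessed` attribute naming criteria that could not be evaluated.
#' @export
referral_criteria <- function(state, thresholds = cdss_thresholds()) {
  met <- character()
  unassessed <- character()
  if (state$panel$egfr_cys < thresholds$egfr_cys_referral) {
    met <- c(met, "egfr_cys_lt30")
  }
  if (is.na(state$potassium)) {
    unassessed <- c(unassessed, "k_gt_5_5")
  } else if (state$potassium > thresholds$k_referral) {
    met <- c(met, "k_gt_5_5")
  }
  if (state$panel$acr > thresholds$acr_referral) {
    met <- c(met, "acr_gt_300")
  }
  if (is.na(state$recent_sbp)) {
    unassessed <- c(unassessed, "sbp_gt150_on_3agents_with_diuretic")
  } else if (state$recent_sbp > thresholds$sbp_referral &&
             state$n_antihypertensive_classes >= thresholds$n_agents_referral &&
             state$has_diuretic) {
    met <- c(met, "sbp_gt150_on_3agents_with_diuretic")
  }
  if (state$kfre_5yr > thresholds$kfre_referral) {
    met <- c(met, "kfre_gt_3pct")
  }
  structure(met, unassessed = unassessed)
}

#' Individualized recommendation set
#'
#' For a low-risk patient the only action is repeat triple-marker testing in
#' 6 months. For a high-risk patient the set is the union of:
#' * `statin_initiation` — age >= 50 and no active statin;
#' * `acei_arb_initiate` / `acei_arb_titrate` — ACR > 30 mg/g without / with
#'   active renin-angiotensin blockade;
#' * `potassium_diet_counseling` — potassium in (5.0, 5.5\];
#'   both potassium actions when potassium > 5.5 mEq/L;
#' * `nephrology_referral` — iff at least one referral criterion is met;
#' * always `bp_target_reminder` and the three education items, in the
#'   patient's preferred language.
#'
#' @param state A [patient_state()].
#' @param thresholds A [cdss_thresholds()].
#' @return A list of class `recommendation_set`: `risk_tier`, `actions`,
#'   `referral_criteria_met`, `unassessed`, `education_language`.
#' @export
recommend <- function(state, thresholds = cdss_thresholds()) {
  tier <- stratify_risk(state$panel$egfr_cys, state$panel$acr, thresholds)
  if (tier == "low") {
    return(structure(list(
      risk_tier = "low",
      actions = "repeat_triple_marker_6mo",
      referral_criteria_met = character(),
      unassessed = character(),
      education_language = state$preferred_language
    ), class = "recommendation_set"))
  }
  actions <- c("bp_target_reminder", EDUCATION_ITEMS)
  if (state$age >= thresholds$statin_age &&
      !("statin" %in% state$active_med_classes)) {
    actions <- c(actions, "statin_initiation")
  }
  if (state$panel$acr > thresholds$acr_high) {
    actions <- c(actions, if ("acei_arb" %in% state$active_med_classes) {
      "acei_arb_titrate"
    } else {
      "acei_arb_initiate"
    })
  }
  if (!is.na(state$potassium)) {
    if (state$potassium > thresholds$k_referral) {
      actions <- c(actions, "potassium_diet_counseling",
                   "potassium_diuretic_adjustment")
    } else if (state$potassium > thresholds$k_diet_low) {
      actions <- c(actions, "potassium_diet_counseling")
    }
  }
  crit <- referral_criteria(state, thresholds)
  if (length(crit)) actions <- c(actions, "nephrology_referral")
  structure(list(
    risk_tier = "high",
    actions = sort(unique(actions)),
    referral_criteria_met = as.character(crit),
    unassessed = attr(crit, "unassessed"),
    education_language = state$preferred_language
  ), class = "recommendation_set")
}

#' @export
print.recommendation_set <- function(x, ...) {
  cat(sprintf("CKD recommendation set (risk tier: %s)\n", x$risk_tier))
  cat("  actions:", paste(x$actions, collapse = ", "), "\n")
  if (length(x$referral_criteria_met)) {
    cat("  referral criteria met:",
        paste(x$referral_criteria_met, collapse = ", "), "\n")
  }
  if (length(x$unassessed)) {
    cat("  unassessed:", paste(x$unassessed, collapse = ", "), "\n")
  }
  cat("  education language:", x$education_language, "\n")
  invisible(x)
}
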