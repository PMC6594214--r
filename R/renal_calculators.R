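# Published renal equations consumed by the decision-support logic:
# CKD-EPI 2009 (creatinine), CKD-EPI 2012 (cystatin C), and the 4-variable
# 5-year kidney failure risk equation (KFRE, North-American calibration).
# Coefficients are taken from the published sources; none are re-derived here.

#' Estimated GFR from serum creatinine (CKD-EPI 2009)
#'
#' Computes eGFR in mL/min/1.73m^2 from serum creatinine using the CKD-EPI
#' 2009 piecewise power-law equation:
#' \deqn{141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
#'       \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot
#'       1.018\,[\mathrm{female}] \cdot 1.159\,[\mathrm{Black,\ if\ enabled}]}
#' with \eqn{\kappa = 0.7} (female) or 0.9 (male) and \eqn{\alpha = -0.329}
#' (female) or \eqn{-0.411} (male).
#'
#' The 2009 race coefficient is behind `race_coefficient_enabled` and is OFF
#' by default; when enabled it multiplies by 1.159 for patients flagged
#' `black`. The flag exists because source laboratories of the study era
#' differed in whether they applied it.
#'
#' @param scr Serum creatinine, mg/dL (> 0). Vectorized.
#' @param age Age in years (>= 18).
#' @param sex `"female"` or `"male"`.
#' @param race_coefficient_enabled Apply the 2009 race coefficient? Default `FALSE`.
#' @param black Logical; only consulted when the race coefficient is enabled.
#' @return eGFR in mL/min/1.73m^2.
#' @examples
#' egfr_creatinine(0.7, age = 40, sex = "female") # ~108.4
#' @export
egfr_creatinine <- function(scr, age, sex, race_coefficient_enabled = FALSE,
                            black = FALSE) {
  check_that(all(is.finite(scr) & scr > 0), "scr", "serum creatinine must be positive")
  check_that(all(is.finite(age) & age >= 18), "age", "adult equation requires age >= 18")
  sex <- match_sex(sex)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  out <- 141 *
    pmin(scr / kappa, 1)^alpha *
    pmax(scr / kappa, 1)^-1.209 *
    0.993^age *
    ifelse(female, 1.018, 1)
  if (isTRUE(race_coefficient_enabled)) {
    out <- out * ifelse(rep_len(black, length(out)), 1.159, 1)
  }
  out
}

#' Estimated GFR from serum cystatin C (CKD-EPI 2012)
#'
#' \deqn{133 \cdot \min(S_{cys}/0.8, 1)^{-0.499} \cdot
#'       \max(S_{cys}/0.8, 1)^{-1.328} \cdot 0.996^{age} \cdot
#'       0.932\,[\mathrm{female}]}
#'
#' @param scys Serum cystatin C, mg/L (> 0). Vectorized.
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @return eGFR in mL/min/1.73m^2.
#' @examples
#' egfr_cystatin(0.8, age = 60, sex = "male") # ~104.6
#' @export
egfr_cystatin <- function(scys, age, sex) {
  check_that(all(is.finite(scys) & scys > 0), "scys", "serum cystatin C must be positive")
  check_that(all(is.finite(age) & age >= 0), "age", "age must be nonnegative")
  sex <- match_sex(sex)
  female <- sex == "female"
  133 *
    pmin(scys / 0.8, 1)^-0.499 *
    pmax(scys / 0.8, 1)^-1.328 *
    0.996^age *
    ifelse(female, 0.932, 1)
}

#' Five-year kidney failure risk (4-variable KFRE)
#'
#' The Tangri 4-variable kidney failure risk equation (age, sex, eGFR, urine
#' ACR), 5-year horizon, North-American calibration. The linear predictor is
#' \deqn{-0.2201(age/10 - 7.036) + 0.2467(male - 0.5642)
#'       - 0.5567(eGFR/5 - 7.222) + 0.4510(\ln ACR - 5.137)}
#' and the risk is \eqn{1 - 0.9240^{\exp(lp)}}.
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param egfr eGFR in mL/min/1.73m^2 (> 0).
#' @param acr Urine albumin-creatinine ratio, mg/g (> 0).
#' @return Probability of kidney failure within 5 years, in (0, 1).
#' @examples
#' kfre_5yr(age = 65, sex = "male", egfr = 25, acr = 500) # ~0.43
#' @export
kfre_5yr <- function(age, sex, egfr, acr) {
  check_that(all(is.finite(egfr) & egfr > 0), "egfr", "eGFR must be positive")
  check_that(all(is.finite(acr) & acr > 0), "acr", "ACR must be positive")
  check_that(all(is.finite(age) & age >= 18), "age", "adult equation requires age >= 18")
  sex <- match_sex(sex)
  male <- as.numeric(sex == "male")
  lp <- -0.2201 * (age / 10 - 7.036) +
    0.2467 * (male - 0.5642) -
    0.5567 * (egfr / 5 - 7.222) +
    0.4510 * (log(acr) - 5.137)
  1 - 0.9240^exp(lp)
}

#' Assemble a triple-marker panel
#'
#' Bundles the three study analytes with their derived eGFRs. `completed_at`
#' is the latest of the three collection timestamps — the time from which the
#' decision-support trigger becomes armed.
#'
#' @param scr,scys,acr Analyte values (creatinine mg/dL, cystatin C mg/L, ACR mg/g).
#' @param age,sex Demographics used for the derived eGFRs.
#' @param collected_at Vector (length 3 or 1) of collection dates for
#'   creatinine, cystatin C, ACR in that order.
#' @param race_coefficient_enabled Passed to [egfr_creatinine()].
#' @return A list of class `triple_marker_panel` with elements `scr`, `scys`,
#'   `acr`, `egfr_cr`, `egfr_cys`, `completed_at`.
#' @export
triple_marker_panel <- function(scr, scys, acr, age, sex, collected_at = Sys.Date(),
                                race_coefficient_enabled = FALSE) {
  collected_at <- rep_len(as.Date(collected_at), 3L)
  structure(
    list(
      scr = scr, scys = scys, acr = acr,
      egfr_cr = egfr_creatinine(scr, age, sex, race_coefficient_enabled),
      egfr_cys = egfr_cystatin(scys, age, sex),
      completed_at = max(collected_at)
    ),
    class = "triple_marker_panel"
  )
}

match_sex <- function(sex) {
  sex <- as.character(sex)
  check_that(all(sex %in% c("female", "male")), "sex", "must be 'female' or 'male'")
  sex
}

# Invert the CKD-EPI 2009 creatinine equation: the creatinine value that
# yields `target` eGFR for the given covariates. Used by the synthetic
# generator to plant labs with known eGFR, so eligibility labels are exact.
invert_egfr_creatinine <- function(target, age, sex) {
  sex <- match_sex(sex)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  base <- 141 * 0.993^age * ifelse(female, 1.018, 1) # value at scr == kappa
  ratio <- target / base
  ifelse(ratio >= 1, kappa * ratio^(1 / alpha), kappa * ratio^(-1 / 1.209))
}
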