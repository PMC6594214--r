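mk_state <- function(egfr_cys = 45, acr = 50, age = 62, sex = "male",
                     potassium = 4.2, sbp = 130, meds = character(),
                     kfre = 0.01, language = "English") {
  patient_state(age = age, sex = sex,
                panel = list(egfr_cys = egfr_cys, acr = acr),
                potassium = potassium, recent_sbp = sbp,
                active_med_classes = meds, preferred_language = language,
                kfre = kfre)
}

test_that("risk stratification: high iff eGFR_Cys < 60 and/or ACR > 30", {
  expect_equal(stratify_risk(55, 10), "high")
  expect_equal(stratify_risk(70, 20), "low")
  expect_equal(stratify_risk(70, 100), "high") # ACR alone suffices
  # boundary values sit in neither printed clause -> low by convention
  expect_equal(stratify_risk(60, 30), "low")
  expect_equal(stratify_risk(59.999, 30), "high")
  expect_equal(stratify_risk(60, 30.001), "high")
  expect_error(stratify_risk(0, 10), "egfr_cys")
  expect_error(stratify_risk(50, -1), "acr")
})

test_that("referral criteria use strict comparators as printed", {
  expect_equal(as.character(referral_criteria(mk_state(egfr_cys = 25))),
               "egfr_cys_lt30")
  expect_length(referral_criteria(mk_state(egfr_cys = 30)), 0) # strict <30
  # SBP rule needs >150 AND >=3 agents AND a diuretic
  no_diur <- mk_state(sbp = 155, meds = c("acei_arb", "beta_blocker", "ccb"))
  expect_length(referral_criteria(no_diur), 0)
  with_diur <- mk_state(sbp = 155,
                        meds = c("acei_arb", "beta_blocker", "thiazide_diuretic"))
  expect_equal(as.character(referral_criteria(with_diur)),
               "sbp_gt150_on_3agents_with_diuretic")
  expect_length(referral_criteria(mk_state(sbp = 150, meds = with_diur$active_med_classes)),
                0) # strict >150
  expect_equal(as.character(referral_criteria(mk_state(kfre = 0.04))),
               "kfre_gt_3pct")
  expect_length(referral_criteria(mk_state(kfre = 0.03)), 0) # strict >3%
  expect_length(referral_criteria(mk_state(potassium = 5.5)), 0) # strict >5.5
  expect_equal(as.character(referral_criteria(mk_state(potassium = 5.6))),
               "k_gt_5_5")
  expect_equal(as.character(referral_criteria(mk_state(acr = 301))),
               "acr_gt_300")
})

test_that("a missing potassium leaves that criterion unmet but flagged unassessed", {
  crit <- referral_criteria(mk_state(potassium = NA))
  expect_false("k_gt_5_5" %in% crit)
  expect_true("k_gt_5_5" %in% attr(crit, "unassessed"))
  rec <- recommend(mk_state(potassium = NA))
  expect_false(any(grepl("potassium", rec$actions)))
})

test_that("low-risk patients get exactly the repeat-testing action", {
  rec <- recommend(mk_state(egfr_cys = 75, acr = 12))
  expect_equal(rec$risk_tier, "low")
  expect_identical(rec$actions, "repeat_triple_marker_6mo")
  expect_length(rec$referral_criteria_met, 0)
})

test_that("high-risk recommendations follow the five care domains", {
  # statin: age >= 50 and not already on one
  expect_true("statin_initiation" %in% recommend(mk_state(age = 62))$actions)
  expect_false("statin_initiation" %in% recommend(mk_state(age = 45))$actions)
  expect_false("statin_initiation" %in%
                 recommend(mk_state(age = 62, meds = "statin"))$actions)
  expect_true("statin_initiation" %in% recommend(mk_state(age = 50))$actions)
  # renin-angiotensin blockade: initiate vs titrate on ACR > 30
  on_acei <- recommend(mk_state(acr = 200, meds = "acei_arb"))
  expect_true("acei_arb_titrate" %in% on_acei$actions)
  expect_false("acei_arb_initiate" %in% on_acei$actions)
  off_acei <- recommend(mk_state(acr = 200))
  expect_true("acei_arb_initiate" %in% off_acei$actions)
  expect_false("acei_arb_titrate" %in% off_acei$actions)
  expect_false(any(grepl("acei_arb", recommend(mk_state(egfr_cys = 45, acr = 20))$actions)))
  # potassium tiers: (5.0, 5.5] diet only; > 5.5 both actions
  diet <- recommend(mk_state(potassium = 5.2))$actions
  expect_true("potassium_diet_counseling" %in% diet)
  expect_false("potassium_diuretic_adjustment" %in% diet)
  both <- recommend(mk_state(potassium = 5.8))$actions
  expect_true(all(c("potassium_diet_counseling",
                    "potassium_diuretic_adjustment") %in% both))
  expect_false("potassium_diet_counseling" %in%
                 recommend(mk_state(potassium = 5.0))$actions)
  # education and BP reminder always present for high risk, in the
  # patient's language
  rec <- recommend(mk_state(language = "Spanish"))
  expect_true(all(c("bp_target_reminder", "education_ckd_general",
                    "education_nsaid_avoidance", "education_diet") %in%
                    rec$actions))
  expect_equal(rec$education_language, "Spanish")
})

test_that("nephrology referral appears iff at least one criterion is met", {
  set.seed(14)
  for (i in 1:300) {
    st <- random_state()
    rec <- recommend(st)
    if (rec$risk_tier == "low") {
      expect_identical(rec$actions, "repeat_triple_marker_6mo")
    } else {
      expect_equal("nephrology_referral" %in% rec$actions,
                   length(rec$referral_criteria_met) > 0)
    }
  }
})

test_that("raising ACR or lowering eGFR_Cys never lowers the risk tier", {
  set.seed(15)
  for (i in 1:200) {
    egfr <- runif(1, 10, 110)
    acr <- exp(runif(1, 0, 7))
    t0 <- stratify_risk(egfr, acr)
    t_worse <- stratify_risk(egfr * runif(1, 0.3, 1), acr * runif(1, 1, 5))
    expect_false(t0 == "high" && t_worse == "low")
  }
})
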