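enroll <- as.Date("2017-10-04")
period_end <- enroll + 365

test_that("the reference fixture reproduces the trial's reported funnel", {
  fx <- example_trial_fixture()
  fr <- funnel_report(fx$event_log, fx$patient_arms)
  p <- setNames(fr$proportions$percent, fr$proportions$stage)
  expect_equal(unname(p["triple_marker_completed"]), 53.0)
  expect_equal(unname(p["pcp_visit_after_labs"]), 77.5)
  expect_equal(unname(p["bpa_opened"]), 73.9)
  expect_equal(unname(p["smartset_signed"]), 81.4)
  # "of all intervention participants" variants
  all_iv <- setNames(fr$of_all_intervention$percent,
                     fr$of_all_intervention$stage)
  expect_equal(unname(all_iv["pcp_visit_after_labs"]), 41.1)
  expect_equal(unname(all_iv["bpa_opened"]), 30.4)
})

test_that("funnel proportions handle empty logs and are monotone on simulations", {
  pats <- data.frame(patient_id = c("a", "b"), arm = c("ecdss", "ecdss_plus"))
  empty <- funnel_report(example_trial_fixture()$event_log[0, ], pats)
  expect_equal(empty$proportions$numerator, rep(0L, 5))
  expect_true(all(is.na(empty$proportions$percent[2:5]))) # zero denominators
  ehr_pats <- data.frame(patient_id = sprintf("p%03d", 1:150),
                         provider_id = "P001",
                         arm = rep(c("ecdss", "ecdss_plus", "usual_care"), 50))
  log <- simulate_trial(ehr_pats, seed = 3)
  fr <- funnel_report(log, ehr_pats)
  n <- fr$stages$pooled
  expect_true(all(diff(n[1:5]) <= 0)) # enrolled >= completed >= ... >= signed
})

test_that("illegal event logs are rejected with the first violation named", {
  pats <- data.frame(patient_id = "a", arm = "ecdss")
  bad <- data.frame(patient_id = "a", arm = "ecdss", kind = "bpa_opened",
                    at = enroll, risk_tier = NA_character_)
  expect_error(funnel_report(bad, pats), "bpa_opened without bpa_displayed")
  unknown <- data.frame(patient_id = "a", arm = "ecdss", kind = "nonsense",
                        at = enroll, risk_tier = NA_character_)
  expect_error(funnel_report(unknown, pats), "unknown event kind")
})

test_that("baseline BP is the most recent ambulatory measurement before enrollment", {
  enc <- bp_encounters(c(-200, -10), sbp = c(150, 142), dbp = c(95, 88))
  b <- baseline_bp(enc, enroll)
  expect_equal(b$sbp, 142)
  expect_equal(b$date, enroll - 10)
  # post-enrollment only -> none
  expect_null(baseline_bp(bp_encounters(5, 120, 80), enroll))
  # same-date tie broken by encounter id (later row wins)
  tie <- bp_encounters(c(-10, -10), sbp = c(150, 130), dbp = c(90, 80))
  expect_equal(baseline_bp(tie, enroll)$sbp, 130)
  # non-ambulatory encounters are invisible
  phone <- bp_encounters(-5, 100, 60, type = "phone")
  expect_equal(baseline_bp(rbind(enc, phone), enroll)$sbp, 142)
})

test_that("BP outcomes implement LOCF, control, and sustained control", {
  # 150/95 baseline, then 138/85 and 136/88: last two consecutive controlled
  enc <- bp_encounters(c(-30, 60, 120), sbp = c(150, 138, 136),
                       dbp = c(95, 85, 88))
  out <- bp_outcomes(enc, enroll, period_end)
  expect_equal(out$baseline_sbp, 150)
  expect_equal(out$endpoint_sbp, 136)
  expect_equal(out$delta_sbp, -14)
  expect_true(out$controlled_at_endpoint)
  expect_true(out$sustained_control)
  # alternating control never gives 2 consecutive controlled visits
  alt <- bp_encounters(c(-30, 30, 90, 150), sbp = c(150, 138, 150, 138),
                       dbp = c(95, 85, 95, 85))
  expect_false(bp_outcomes(alt, enroll, period_end)$sustained_control)
  # a single controlled in-period visit: controlled endpoint, not sustained
  one <- bp_encounters(c(-30, 60), sbp = c(150, 130), dbp = c(95, 80))
  o1 <- bp_outcomes(one, enroll, period_end)
  expect_true(o1$controlled_at_endpoint)
  expect_false(o1$sustained_control)
  # boundary: 140/90 exactly is NOT controlled (strict thresholds)
  b <- bp_outcomes(bp_encounters(c(-30, 60), sbp = c(150, 140),
                                 dbp = c(95, 88)), enroll, period_end)
  expect_false(b$controlled_at_endpoint)
})

test_that("LOCF endpoint never post-dates the period and falls back to baseline", {
  enc <- bp_encounters(c(-30, 100, 500), sbp = c(150, 135, 120),
                       dbp = c(95, 85, 75))
  out <- bp_outcomes(enc, enroll, period_end)
  expect_equal(out$endpoint_sbp, 135) # day-500 measurement is out of period
  expect_lte(as.numeric(out$endpoint_date - period_end), 0)
  # no in-period measurements: baseline carried forward, delta 0
  none <- bp_outcomes(bp_encounters(-30, 150, 95), enroll, period_end)
  expect_equal(none$delta_sbp, 0)
  expect_equal(none$n_inperiod_measurements, 0)
  # no baseline at all -> excluded with a reason
  miss <- bp_outcomes(bp_encounters(60, 130, 80), enroll, period_end)
  expect_s3_class(miss, "bp_outcome_missing")
  expect_equal(attr(miss, "reason"), "no_baseline")
})

test_that("process outcomes reproduce known numerators over 524 patients", {
  n <- 524
  pats <- data.frame(patient_id = sprintf("q%04d", 1:n),
                     birth_date = enroll - round(70 * 365.25),
                     arm = rep(c("usual_care", "ecdss", "ecdss_plus"),
                               length.out = n))
  # 61 on the problem list; another 186 with a visit diagnosis only -> 247 total
  pl <- rbind(
    data.frame(patient_id = pats$patient_id[1:61], condition = "ckd",
               source = "problem_list"),
    data.frame(patient_id = pats$patient_id[62:247], condition = "ckd",
               source = "visit_diagnosis"))
  meds <- data.frame(patient_id = pats$patient_id[1:100], med_class = "statin",
                     active_from = enroll - 500, active_to = as.Date(NA))
  out <- process_outcomes(pats, meds, pl, acr = NULL,
                          period = c(enroll, period_end))
  pooled <- out[out$arm == "pooled", ]
  expect_equal(pooled$percent[pooled$measure == "ckd_recognized"], 47.1)
  expect_equal(pooled$numerator[pooled$measure == "ckd_recognized"], 247)
  expect_equal(pooled$percent[pooled$measure == "ckd_on_problem_list"], 11.6)
  expect_equal(pooled$numerator[pooled$measure == "ckd_on_problem_list"], 61)
  # no albuminuria data -> zero denominator, NA proportion
  alb <- pooled[pooled$measure == "acei_arb_for_albuminuria", ]
  expect_equal(alb$denominator, 0)
  expect_true(is.na(alb$percent))
  # all patients are 70, so the statin denominator is everyone
  st <- pooled[pooled$measure == "statin_age50plus", ]
  expect_equal(st$denominator, n)
  expect_equal(st$numerator, 100)
})

test_that("statin initiation counts only in-period starts among the naive", {
  pats <- data.frame(patient_id = c("a", "b", "c"),
                     birth_date = enroll - round(60 * 365.25),
                     arm = "ecdss")
  meds <- data.frame(
    patient_id = c("a", "b"), med_class = "statin",
    active_from = c(enroll - 300, enroll + 60), active_to = as.Date(NA))
  out <- process_outcomes(pats, meds, data.frame(patient_id = character(),
                                                 condition = character(),
                                                 source = character()),
                          acr = data.frame(patient_id = "c", acr = 120),
                          period = c(enroll, period_end))
  pooled <- out[out$arm == "pooled", ]
  init <- pooled[pooled$measure == "statin_initiated_in_period", ]
  expect_equal(init$numerator, 1) # only b
  expect_equal(init$denominator, 2) # b and c were naive at baseline
  alb <- pooled[pooled$measure == "acei_arb_for_albuminuria", ]
  expect_equal(alb$denominator, 1)
  expect_equal(alb$numerator, 0)
})
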