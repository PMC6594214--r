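d0 <- as.Date("2018-01-01")

pcp_enc <- function(day, type = "pcp_visit", provider = "P001") {
  list(occurred_at = d0 + day, type = type, provider_id = provider)
}

test_that("panel completion time is the max of the three results", {
  res <- data.frame(analyte = c("serum_creatinine", "cystatin_c", "urine_acr"),
                    collected_at = d0 + c(3, 5, 9))
  expect_equal(labs_complete_time(res), d0 + 9)
  expect_equal(labs_complete_time(res[res$collected_at == d0 + 3, , drop = FALSE]),
               as.Date(NA)) # ACR missing
  same_day <- data.frame(analyte = c("serum_creatinine", "cystatin_c", "urine_acr"),
                         collected_at = d0 + 4)
  expect_equal(labs_complete_time(same_day), d0 + 4)
  dup <- rbind(res, data.frame(analyte = "urine_acr", collected_at = d0 + 15))
  expect_warning(out <- labs_complete_time(dup), "duplicate")
  expect_equal(out, d0 + 15)
})

test_that("the alert displays only at an armed own-PCP visit", {
  st <- trigger_state("pt1", "ecdss", pcp_id = "P001")
  # before labs complete: nothing
  r <- process_encounter(st, pcp_enc(5))
  expect_equal(nrow(r$events), 0)
  st <- r$state
  st$labs_complete_at <- d0 + 10
  # non-PCP visit after labs: nothing
  r <- process_encounter(st, pcp_enc(20, provider = "P999"))
  expect_equal(nrow(r$events), 0)
  # nephrology visit with own provider id: still not a pcp_visit
  r <- process_encounter(r$state, pcp_enc(21, type = "nephrology_visit"))
  expect_equal(nrow(r$events), 0)
  # own-PCP visit on the completion day itself: displays
  r <- process_encounter(r$state, pcp_enc(25))
  expect_equal(r$events$kind, "bpa_displayed")
  expect_equal(r$state$displays, 1L)
})

test_that("three unsigned displays exhaust the alert", {
  st <- trigger_state("pt1", "ecdss", pcp_id = "P001")
  st$labs_complete_at <- d0
  for (day in c(10, 20, 30)) {
    r <- process_encounter(st, pcp_enc(day))
    expect_equal(r$events$kind, "bpa_displayed")
    st <- r$state
  }
  expect_equal(st$displays, 3L)
  r4 <- process_encounter(st, pcp_enc(40))
  expect_equal(nrow(r4$events), 0)
})

test_that("signing is absorbing and schedules the pharmacist task in eCDSS+", {
  st <- trigger_state("pt1", "ecdss_plus", pcp_id = "P001")
  st$labs_complete_at <- d0 + 50
  r <- process_encounter(st, pcp_enc(100), behavior = list(opens = TRUE,
                                                           signs = TRUE))
  expect_equal(r$events$kind, c("bpa_displayed", "bpa_opened",
                                "smartset_signed", "pharmacist_call_scheduled"))
  st <- r$state
  expect_true(st$signed)
  expect_equal(st$pharmacist_task$due_by, d0 + 114) # sign day + 14
  # later PCP visits emit nothing
  r2 <- process_encounter(st, pcp_enc(120), behavior = list(opens = TRUE,
                                                            signs = TRUE))
  expect_equal(nrow(r2$events), 0)
  # out-of-order encounters are a sequencing error
  expect_error(process_encounter(st, pcp_enc(90)), "chronological")
})

test_that("pharmacist scheduling enforces its contract", {
  st <- trigger_state("pt1", "ecdss", pcp_id = "P001")
  st$signed <- TRUE; st$signed_at <- d0
  expect_error(schedule_pharmacist_call(st), "ecdss_plus")
  st2 <- trigger_state("pt2", "ecdss_plus", pcp_id = "P001")
  expect_error(schedule_pharmacist_call(st2), "signed")
  st2$signed <- TRUE; st2$signed_at <- d0 + 100
  task <- schedule_pharmacist_call(st2)
  expect_equal(task$due_by, d0 + 114)
  st2$pharmacist_task <- task
  expect_error(schedule_pharmacist_call(st2), "already")
})

test_that("the trial simulator saturates and starves correctly", {
  pats <- data.frame(patient_id = sprintf("pt%03d", 1:60),
                     provider_id = "P001",
                     arm = rep(c("usual_care", "ecdss", "ecdss_plus"), 20))
  all_on <- list(p_lab_completion = 1, p_pcp_visit = 1, p_open = 1,
                 p_sign = 1, p_call_completed = 1)
  log <- simulate_trial(pats, behavior = all_on, seed = 5)
  fr <- funnel_report(log, pats)
  expect_true(all(fr$proportions$percent[1:4] == 100))
  expect_equal(fr$stages$pooled[fr$stages$stage == "enrolled"], 40)
  # usual-care patients emit nothing
  expect_false(any(log$arm == "usual_care"))
  # no labs -> no displays at all
  off <- simulate_trial(pats, behavior = within(all_on, p_lab_completion <- 0),
                        seed = 5)
  expect_false(any(off$kind %in% c("lab_completed", "bpa_displayed")))
  # replay determinism
  expect_identical(log, simulate_trial(pats, behavior = all_on, seed = 5))
  expect_error(simulate_trial(pats, behavior = within(all_on, p_open <- 2)),
               "p_open")
})

test_that("simulated funnel counts match the behavior probabilities", {
  pats <- data.frame(patient_id = sprintf("pt%04d", 1:336),
                     provider_id = "P001",
                     arm = rep(c("ecdss", "ecdss_plus"), length.out = 336))
  beh <- list(p_lab_completion = 0.53, p_pcp_visit = 0.775, p_open = 0.739,
              p_sign = 0.814, p_call_completed = 0.9)
  log <- simulate_trial(pats, behavior = beh, seed = 20)
  fr <- funnel_report(log, pats)
  n <- setNames(fr$stages$pooled, fr$stages$stage)
  # expected counts 178 / 138 / 102 / 83; binomial tolerance (4 sd of the
  # stage count given 336 starters)
  expected <- 336 * cumprod(c(beh$p_lab_completion, beh$p_pcp_visit,
                              beh$p_open, beh$p_sign))
  observed <- unname(n[c("triple_marker_completed", "pcp_visit_after_labs",
                         "bpa_opened", "smartset_signed")])
  tol <- 4 * sqrt(expected * (1 - expected / 336))
  expect_true(all(abs(observed - expected) < tol))
})

test_that("event logs round-trip through JSON lines", {
  fx <- example_trial_fixture()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(fx$event_log, path)
  back <- read_event_log(path)
  expect_equal(back$patient_id, fx$event_log$patient_id)
  expect_equal(back$kind, fx$event_log$kind)
  expect_equal(back$at, fx$event_log$at)
})
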