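# Reference fixture encoding the trial's reported participant flow, built
# programmatically so the funnel machinery can be exercised against known
# totals: 336 intervention patients of whom 178 completed triple-marker
# labs, 138 had an own-PCP visit afterwards, 102 had the alert opened and
# 83 had orders signed; and a selection cascade of 995 initially eligible
# patients with 316 automated exclusions, 97 manual/clinician exclusions
# and 58 opt-outs/withdrawals leaving 524 included.

#' Reference trial-flow fixture
#'
#' Builds, in code, an event log and patient/arm roster matching the
#' implementation funnel above (stage membership nested within each arm:
#' eCDSS n=165, eCDSS+ n=171), and an eligibility decisions table matching
#' the selection cascade. Feed `event_log` + `patient_arms` to
#' [funnel_report()] and `decisions` to [selection_funnel()].
#'
#' @return List with `event_log`, `patient_arms`, `decisions`.
#' @export
example_trial_fixture <- function() {
  n_ecdss <- 165L
  n_plus <- 171L
  start <- as.Date("2017-10-04")
  patient_arms <- data.frame(
    patient_id = sprintf("FX%04d", seq_len(n_ecdss + n_plus)),
    arm = c(rep("ecdss", n_ecdss), rep("ecdss_plus", n_plus)),
    stringsAsFactors = FALSE
  )
  # per-arm stage counts summing to the pooled funnel 178/138/102/83
  stage_counts <- list(ecdss = c(completed = 89L, visited = 69L, opened = 51L,
                                 signed = 41L),
                       ecdss_plus = c(completed = 89L, visited = 69L,
                                      opened = 51L, signed = 42L))
  rows <- list()
  for (a in names(stage_counts)) {
    ids <- patient_arms$patient_id[patient_arms$arm == a]
    sc <- stage_counts[[a]]
    for (i in seq_along(ids)) {
      pid <- ids[i]
      rows[[length(rows) + 1L]] <- new_event(pid, a, "triple_order", start)
      if (i > sc[["completed"]]) next
      rows[[length(rows) + 1L]] <- new_event(pid, a, "lab_completed", start + 30)
      if (i > sc[["visited"]]) next
      rows[[length(rows) + 1L]] <- new_event(pid, a, "bpa_displayed", start + 90)
      if (i > sc[["opened"]]) next
      rows[[length(rows) + 1L]] <- new_event(pid, a, "bpa_opened", start + 90)
      if (i > sc[["signed"]]) next
      rows[[length(rows) + 1L]] <- new_event(pid, a, "smartset_signed", start + 90)
      if (a == "ecdss_plus") {
        rows[[length(rows) + 1L]] <-
          new_event(pid, a, "pharmacist_call_scheduled", start + 90)
        if (i <= 38L) { # calls completed within the 2-week window
          rows[[length(rows) + 1L]] <-
            new_event(pid, a, "pharmacist_call_completed", start + 100)
        }
      }
    }
  }
  event_log <- do.call(rbind, rows)
  class(event_log) <- c("trial_event_log", "data.frame")

  # selection cascade: 1100 screened -> 995 initially eligible -> 316
  # automated -> 97 manual -> 582 distributed -> 58 opt-out -> 524 included
  reason <- c(rep("age_range", 105L),
              rep(c("deceased", "esrd", "nephrology_engaged", "transplant",
                    "dementia"), length.out = 316L),
              rep("manual_exclusion:pcp_discretion", 97L),
              rep("opt_out", 58L),
              rep("", 524L))
  decisions <- data.frame(
    patient_id = sprintf("SC%04d", seq_along(reason)),
    eligible = reason == "",
    reason_codes = reason,
    stringsAsFactors = FALSE
  )
  list(event_log = event_log, patient_arms = patient_arms,
       decisions = decisions)
}
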