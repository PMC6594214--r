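# Best-practice-advisory (BPA) lifecycle. The alert arms once all three
# triple-marker results are in, fires at the first visit the patient has
# with their own PCP after that, and — if not opened-and-signed — may fire
# at up to 2 additional own-PCP visits (3 display opportunities total).
# Signing is absorbing. In the eCDSS+ arm a signed SmartSet schedules a
# pharmacist phone call due within 14 days of signing.

MAX_BPA_DISPLAYS <- 3L

EVENT_KINDS <- c("triple_order", "lab_completed", "bpa_displayed",
                 "bpa_opened", "smartset_signed", "pharmacist_call_scheduled",
                 "pharmacist_call_completed")

#' Initialize a BPA trigger state
#'
#' @param patient_id Patient identifier.
#' @param arm `"usual_care"`, `"ecdss"` or `"ecdss_plus"`.
#' @param pcp_id The patient's own PCP (panel assignment at trial start);
#'   visits with any other provider never trigger the alert.
#' @param max_displays Display-opportunity cap; default 3 (the first
#'   eligible visit plus up to 2 more).
#' @return A list of class `trigger_state`.
#' @export
trigger_state <- function(patient_id, arm, pcp_id,
                          max_displays = MAX_BPA_DISPLAYS) {
  check_that(arm %in% c("usual_care", "ecdss", "ecdss_plus"), "arm",
             "unknown arm label")
  structure(list(
    patient_id = patient_id, arm = arm, pcp_id = pcp_id,
    labs_complete_at = as.Date(NA), displays = 0L,
    opened = FALSE, signed = FALSE, signed_at = as.Date(NA),
    pharmacist_task = NULL, max_displays = as.integer(max_displays),
    last_seen_at = as.Date("0001-01-01")
  ), class = "trigger_state")
}

#' Completion time of the triple-marker panel
#'
#' The alert arms only when all three analytes (serum creatinine, cystatin
#' C, urine ACR) have resulted; the completion time is the latest of the
#' three collection timestamps. Duplicate results for an analyte use the
#' latest value, with a warning.
#'
#' @param panel_results Data frame with columns `analyte` and `collected_at`.
#' @return The completion date, or `NA` if any analyte is missing.
#' @export
labs_complete_time <- function(panel_results) {
  needed <- c("serum_creatinine", "cystatin_c", "urine_acr")
  if (is.null(panel_results) || nrow(panel_results) == 0) return(as.Date(NA))
  res <- panel_results[panel_results$analyte %in% needed, ]
  if (anyDuplicated(res$analyte)) {
    warning("duplicate analyte results; using the latest per analyte")
    res <- res[order(res$analyte, as.Date(res$collected_at)), ]
    res <- res[!duplicated(res$analyte, fromLast = TRUE), ]
  }
  if (!all(needed %in% res$analyte)) return(as.Date(NA))
  max(as.Date(res$collected_at))
}

new_event <- function(patient_id, arm, kind, at, risk_tier = NA_character_) {
  data.frame(patient_id = patient_id, arm = arm, kind = kind,
             at = as.Date(at), risk_tier = risk_tier, stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(patient_id = character(), arm = character(), kind = character(),
             at = as.Date(character()), risk_tier = character(),
             stringsAsFactors = FALSE)
}

#' Advance the trigger state machine by one encounter
#'
#' The BPA is displayed iff the encounter is a `pcp_visit` with the
#' patient's own PCP, the triple-marker panel has completed on or before the
#' encounter date, the SmartSet has not been signed, and fewer than
#' `max_displays` displays have occurred. The `behavior` flags then decide
#' whether the PCP opens (accept click — hovering does not count) and, if
#' opened, signs; signing freezes the machine.
#'
#' @param state A [trigger_state()].
#' @param encounter List or one-row data frame with `occurred_at`, `type`,
#'   `provider_id`.
#' @param behavior List with logicals `opens` and `signs`.
#' @param risk_tier Optional recommendation snapshot recorded on display.
#' @return List with updated `state` and an `events` data frame (possibly
#'   empty) of emitted trial events.
#' @export
process_encounter <- function(state, encounter, behavior = list(opens = FALSE,
                                                                signs = FALSE),
                              risk_tier = NA_character_) {
  stopifnot(inherits(state, "trigger_state"))
  at <- as.Date(encounter$occurred_at)
  if (at < state$last_seen_at) {
    stop("encounters must be processed in chronological order", call. = FALSE)
  }
  state$last_seen_at <- at
  events <- empty_events()
  displayable <- identical(encounter$type, "pcp_visit") &&
    identical(encounter$provider_id, state$pcp_id) &&
    !is.na(state$labs_complete_at) && state$labs_complete_at <= at &&
    !state$signed && state$displays < state$max_displays
  if (displayable) {
    state$displays <- state$displays + 1L
    events <- rbind(events, new_event(state$patient_id, state$arm,
                                      "bpa_displayed", at, risk_tier))
    if (isTRUE(behavior$opens)) {
      state$opened <- TRUE
      events <- rbind(events, new_event(state$patient_id, state$arm,
                                        "bpa_opened", at, risk_tier))
      if (isTRUE(behavior$signs)) {
        state$signed <- TRUE
        state$signed_at <- at
        events <- rbind(events, new_event(state$patient_id, state$arm,
                                          "smartset_signed", at, risk_tier))
        if (state$arm == "ecdss_plus") {
          state$pharmacist_task <- schedule_pharmacist_call(state)
          events <- rbind(events, new_event(state$patient_id, state$arm,
                                            "pharmacist_call_scheduled",
                                            at, risk_tier))
        }
      }
    }
  }
  list(state = state, events = events)
}

#' Schedule the eCDSS+ pharmacist follow-up call
#'
#' Only defined for a signed state in the `ecdss_plus` arm: the call is due
#' within 2 weeks of the visit at which the SmartSet was signed.
#'
#' @param state A signed `trigger_state` with `arm == "ecdss_plus"`.
#' @return List with `due_by` (`signed_at + 14` days) and `completed_at`
#'   (`NA` until the call happens).
#' @export
schedule_pharmacist_call <- function(state) {
  if (!identical(state$arm, "ecdss_plus")) {
    stop("pharmacist calls are scheduled only in the ecdss_plus arm",
         call. = FALSE)
  }
  if (!isTRUE(state$signed) || is.na(state$signed_at)) {
    stop("pharmacist calls are scheduled only after the SmartSet is signed",
         call. = FALSE)
  }
  if (!is.null(state$pharmacist_task)) {
    stop("pharmacist call already scheduled for this patient", call. = FALSE)
  }
  list(due_by = state$signed_at + 14L, completed_at = as.Date(NA))
}

#' Simulate the intervention workflow for a whole trial
#'
#' Runs every intervention-arm patient through the order -> labs -> visit ->
#' BPA -> sign -> (pharmacist call) pipeline under a Bernoulli behavior
#' model. Usual-care patients emit no events. The simulation is a
#' deterministic function of the inputs and `seed`.
#'
#' Behavior gates: the triple-marker panel completes with probability
#' `p_lab_completion` (at a uniform day early in the period); a completer
#' has an own-PCP visit after the labs with probability `p_pcp_visit`; at a
#' displayed alert the PCP opens with probability `p_open` and, having
#' opened, signs with probability `p_sign`; a signed eCDSS+ patient's
#' pharmacist call is completed with probability `p_call_completed`. By
#' default each patient gets `n_visits` = 1 eligible visit, so the expected
#' funnel proportions equal the gate probabilities.
#'
#' @param patients Data frame with `patient_id`, `provider_id` and the
#'   patient's `arm` (e.g. enrolled patients joined to the provider
#'   assignment).
#' @param behavior Named list of the five probabilities above.
#' @param start_date Trial start (triple-marker order date for everyone).
#' @param horizon_days Intervention period length; default 365.
#' @param n_visits Own-PCP visits granted to a patient whose visit gate
#'   passes (1 to `max_displays`).
#' @param risk_tiers Optional named vector (by patient id) of risk-tier
#'   snapshots to stamp on display events.
#' @param seed Integer seed.
#' @return Event log: data frame with `patient_id`, `arm`, `kind`, `at`,
#'   `risk_tier`, ordered by patient and date, of class `trial_event_log`.
#' @export
simulate_trial <- function(patients, behavior = list(p_lab_completion = 0.53,
                                                     p_pcp_visit = 0.775,
                                                     p_open = 0.739,
                                                     p_sign = 0.814,
                                                     p_call_completed = 0.9),
                           start_date = as.Date("2017-10-04"),
                           horizon_days = 365L, n_visits = 1L,
                           risk_tiers = NULL, seed = 1L) {
  for (p in c("p_lab_completion", "p_pcp_visit", "p_open", "p_sign",
              "p_call_completed")) {
    check_that(is_prob(behavior[[p]]), p, "must be a probability in [0,1]")
  }
  check_that(is_count(n_visits) && n_visits <= MAX_BPA_DISPLAYS, "n_visits",
             sprintf("must be an integer in 1..%d", MAX_BPA_DISPLAYS))
  start_date <- as.Date(start_date)
  iv <- patients[patients$arm %in% c("ecdss", "ecdss_plus"), , drop = FALSE]
  with_seed(seed, {
    logs <- lapply(seq_len(nrow(iv)), function(i) {
      pid <- iv$patient_id[i]
      arm <- iv$arm[i]
      tier <- if (!is.null(risk_tiers)) unname(risk_tiers[pid]) else NA_character_
      ev <- new_event(pid, arm, "triple_order", start_date, tier)
      if (stats::rbinom(1, 1, behavior$p_lab_completion) == 0) return(ev)
      lab_day <- start_date + sample.int(min(180L, horizon_days - 2L), 1)
      ev <- rbind(ev, new_event(pid, arm, "lab_completed", lab_day, tier))
      st <- trigger_state(pid, arm, pcp_id = iv$provider_id[i])
      st$labs_complete_at <- lab_day
      if (stats::rbinom(1, 1, behavior$p_pcp_visit) == 0) return(ev)
      remaining <- as.integer(start_date + horizon_days - lab_day) - 1L
      visit_days <- lab_day + sort(sample.int(max(remaining, n_visits),
                                              n_visits))
      for (k in seq_along(visit_days)) {
        vd <- visit_days[k] # keep Date class (bare for() would drop it)
        if (st$signed) break
        beh <- list(opens = stats::runif(1) < behavior$p_open, signs = FALSE)
        if (beh$opens) beh$signs <- stats::runif(1) < behavior$p_sign
        step <- process_encounter(st, list(occurred_at = vd,
                                           type = "pcp_visit",
                                           provider_id = st$pcp_id),
                                  beh, risk_tier = tier)
        st <- step$state
        ev <- rbind(ev, step$events)
      }
      if (!is.null(st$pharmacist_task) &&
          stats::rbinom(1, 1, behavior$p_call_completed) == 1) {
        done <- st$signed_at + sample.int(14L, 1)
        ev <- rbind(ev, new_event(pid, arm, "pharmacist_call_completed",
                                  done, tier))
      }
      ev
    })
    log <- do.call(rbind, c(logs, list(empty_events())))
    log <- log[order(log$patient_id, log$at,
                     match(log$kind, EVENT_KINDS)), ]
    rownames(log) <- NULL
    class(log) <- c("trial_event_log", "data.frame")
    log
  })
}

#' Write / read a trial event log as JSON lines
#'
#' One event per line with ISO-8601 dates.
#'
#' @param log An event-log data frame.
#' @param path File path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the event-log data frame.
#' @export
write_event_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(list(patient_id = log$patient_id[i], arm = log$arm[i],
                          kind = log$kind[i], at = format(log$at[i]),
                          risk_tier = log$risk_tier[i]),
                     auto_unbox = TRUE, na = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(patient_id = x$patient_id, arm = x$arm, kind = x$kind,
               at = as.Date(x$at),
               risk_tier = if (is.null(x$risk_tier)) NA_character_ else x$risk_tier,
               stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, rows)
  class(log) <- c("trial_event_log", "data.frame")
  log
}
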