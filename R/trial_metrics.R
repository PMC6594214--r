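# Implementation-funnel (reach/adoption), process-of-care and blood-pressure
# outcome metrics, computed from the trial event log and EHR tables. Every
# proportion carries its numerator and denominator so each figure can be
# traced to an explicit patient list.

#' Implementation funnel from a trial event log
#'
#' Counts, per arm and pooled across the intervention arms, the patients
#' reaching each stage — enrolled, triple-marker completed, own-PCP visit
#' after labs (= alert displayed at least once), alert opened, SmartSet
#' signed, pharmacist call completed — and the stage-over-previous-stage
#' proportions the trial reports (completion over enrolled, visit over
#' completers, opened over visited, signed over opened, call over signed
#' eCDSS+), plus each stage over all intervention patients. Zero
#' denominators yield `NA` proportions.
#'
#' @param event_log Event-log data frame (see [simulate_trial()]).
#' @param patient_arms Data frame `patient_id`, `arm` for every enrolled
#'   patient (defines the denominators; patients with no events still count
#'   as enrolled).
#' @return A list of class `funnel_report`: `stages` (per-arm and pooled
#'   counts), `proportions` (stage, numerator, denominator, percent), and
#'   `of_all_intervention` variants.
#' @export
funnel_report <- function(event_log, patient_arms) {
  validate_event_log(event_log)
  iv <- patient_arms[patient_arms$arm %in% c("ecdss", "ecdss_plus"), ,
                     drop = FALSE]
  reached <- function(kind, ids = iv$patient_id) {
    unique(event_log$patient_id[event_log$kind == kind &
                                  event_log$patient_id %in% ids])
  }
  stage_sets <- list(
    enrolled = iv$patient_id,
    triple_marker_completed = reached("lab_completed"),
    pcp_visit_after_labs = reached("bpa_displayed"),
    bpa_opened = reached("bpa_opened"),
    smartset_signed = reached("smartset_signed"),
    pharmacist_call_completed = reached("pharmacist_call_completed")
  )
  arms <- c("ecdss", "ecdss_plus")
  stages <- do.call(rbind, lapply(names(stage_sets), function(st) {
    ids <- stage_sets[[st]]
    counts <- vapply(arms, function(a) {
      sum(iv$arm[match(ids, iv$patient_id)] == a, na.rm = TRUE)
    }, 0L)
    data.frame(stage = st, ecdss = counts[["ecdss"]],
               ecdss_plus = counts[["ecdss_plus"]],
               pooled = length(ids), stringsAsFactors = FALSE)
  }))
  n <- stats::setNames(stages$pooled, stages$stage)
  call_den <- length(intersect(stage_sets$smartset_signed,
                               iv$patient_id[iv$arm == "ecdss_plus"]))
  prop <- function(stage, num, den) {
    data.frame(stage = stage, numerator = num, denominator = den,
               percent = pct1(num, den), stringsAsFactors = FALSE)
  }
  proportions <- rbind(
    prop("triple_marker_completed", n[["triple_marker_completed"]], n[["enrolled"]]),
    prop("pcp_visit_after_labs", n[["pcp_visit_after_labs"]],
         n[["triple_marker_completed"]]),
    prop("bpa_opened", n[["bpa_opened"]], n[["pcp_visit_after_labs"]]),
    prop("smartset_signed", n[["smartset_signed"]], n[["bpa_opened"]]),
    prop("pharmacist_call_completed", n[["pharmacist_call_completed"]], call_den)
  )
  of_all <- do.call(rbind, lapply(
    setdiff(names(stage_sets), "enrolled"),
    function(st) prop(st, n[[st]], n[["enrolled"]])))
  structure(list(stages = stages, proportions = proportions,
                 of_all_intervention = of_all),
            class = "funnel_report")
}

# Event-log sanity: known kinds, per-patient monotonicity of the funnel.
validate_event_log <- function(event_log) {
  bad <- setdiff(unique(event_log$kind), EVENT_KINDS)
  if (length(bad)) {
    stop(sprintf("unknown event kind(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  has <- function(kind) unique(event_log$patient_id[event_log$kind == kind])
  chain <- c("lab_completed", "bpa_displayed", "bpa_opened", "smartset_signed")
  for (i in seq_len(length(chain) - 1)) {
    orphan <- setdiff(has(chain[i + 1]), has(chain[i]))
    if (length(orphan)) {
      stop(sprintf("event log violates the funnel: patient %s has %s without %s",
                   orphan[1], chain[i + 1], chain[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Implementation funnel (pooled intervention arms)\n")
  for (i in seq_len(nrow(x$proportions))) {
    p <- x$proportions[i, ]
    cat(sprintf("  %-26s %4d / %4d  (%s%%)\n", p$stage, p$numerator,
                p$denominator,
                ifelse(is.na(p$percent), "n/a", format(p$percent))))
  }
  invisible(x)
}

#' Baseline blood pressure
#'
#' The most recent ambulatory BP measurement strictly before the enrollment
#' date. Same-date ties are broken by encounter id (a stable tiebreak).
#'
#' @param encounters Encounter rows for one patient (`occurred_at`, `type`,
#'   `systolic_bp`, `diastolic_bp`, optional `encounter_id`).
#' @param enrollment_date Enrollment cutoff.
#' @return List `sbp`, `dbp`, `date`, or `NULL` when no prior measurement.
#' @export
baseline_bp <- function(encounters, enrollment_date) {
  enrollment_date <- as.Date(enrollment_date)
  amb <- ambulatory_bp_rows(encounters)
  amb <- amb[as.Date(amb$occurred_at) < enrollment_date, , drop = FALSE]
  if (nrow(amb) == 0) return(NULL)
  key <- order(as.Date(amb$occurred_at),
               if (!is.null(amb$encounter_id)) amb$encounter_id else
                 seq_len(nrow(amb)))
  last <- amb[key[length(key)], ]
  list(sbp = last$systolic_bp, dbp = last$diastolic_bp,
       date = as.Date(last$occurred_at))
}

ambulatory_bp_rows <- function(encounters) {
  if (is.null(encounters) || nrow(encounters) == 0) {
    return(encounters[integer(0), , drop = FALSE])
  }
  keep <- encounters$type %in% c("pcp_visit", "non_pcp_visit",
                                 "nephrology_visit") &
    !is.na(encounters$systolic_bp) & !is.na(encounters$diastolic_bp)
  encounters[keep, , drop = FALSE]
}

#' Blood-pressure outcomes for one patient
#'
#' Endpoint BP is the last in-period ambulatory measurement carried forward
#' (LOCF); deltas are endpoint minus baseline. `controlled_at_endpoint` is
#' endpoint SBP < 140 and DBP < 90 (both strict). `sustained_control` is
#' true iff some run of 2 or more consecutive BP-measured visits within the
#' period all satisfy that threshold — visits without a BP measurement are
#' invisible to the sequence.
#'
#' @param encounters Encounter rows for one patient.
#' @param enrollment_date Baseline cutoff (see [baseline_bp()]).
#' @param period_end End of the observation period (inclusive).
#' @param control_sbp,control_dbp Control thresholds; default < 140 / < 90.
#' @return List of class `bp_outcome`, or `NULL` with attribute
#'   `reason = "no_baseline"` when the patient has no baseline measurement.
#' @export
bp_outcomes <- function(encounters, enrollment_date, period_end,
                        control_sbp = 140, control_dbp = 90) {
  enrollment_date <- as.Date(enrollment_date)
  period_end <- as.Date(period_end)
  base <- baseline_bp(encounters, enrollment_date)
  if (is.null(base)) {
    return(structure(list(), reason = "no_baseline", class = "bp_outcome_missing"))
  }
  amb <- ambulatory_bp_rows(encounters)
  d <- as.Date(amb$occurred_at)
  inp <- amb[d >= enrollment_date & d <= period_end, , drop = FALSE]
  inp <- inp[order(as.Date(inp$occurred_at),
                   if (!is.null(inp$encounter_id)) inp$encounter_id else
                     seq_len(nrow(inp))), , drop = FALSE]
  if (nrow(inp) == 0) {
    endpoint <- base # LOCF falls back to the baseline measurement
    controlled_series <- logical(0)
  } else {
    lastrow <- inp[nrow(inp), ]
    endpoint <- list(sbp = lastrow$systolic_bp, dbp = lastrow$diastolic_bp,
                     date = as.Date(lastrow$occurred_at))
    controlled_series <- inp$systolic_bp < control_sbp &
      inp$diastolic_bp < control_dbp
  }
  runs <- rle(controlled_series)
  sustained <- any(runs$values & runs$lengths >= 2)
  structure(list(
    baseline_sbp = base$sbp, baseline_dbp = base$dbp,
    endpoint_sbp = endpoint$sbp, endpoint_dbp = endpoint$dbp,
    endpoint_date = endpoint$date,
    delta_sbp = endpoint$sbp - base$sbp,
    delta_dbp = endpoint$dbp - base$dbp,
    controlled_at_endpoint = endpoint$sbp < control_sbp &
      endpoint$dbp < control_dbp,
    sustained_control = sustained,
    n_inperiod_measurements = nrow(inp)
  ), class = "bp_outcome")
}

#' Process-of-care proportions
#'
#' Per-arm and pooled proportions with explicit numerators/denominators:
#' * `ckd_recognized` — CKD on the problem list or as a visit diagnosis,
#'   over all patients;
#' * `ckd_on_problem_list` — problem-list entries only;
#' * `acei_arb_for_albuminuria` — active ACEi/ARB among patients with
#'   ACR > 30 mg/g;
#' * `statin_age50plus` — active statin among patients aged >= 50 at
#'   `age_ref_date`;
#' * `statin_initiated_in_period` — statin order starting inside
#'   `period`, over patients not on a statin before it.
#'
#' @param patients Data frame `patient_id`, `birth_date`, `arm`.
#' @param medications Medication orders (`patient_id`, `med_class`,
#'   `active_from`, `active_to`).
#' @param problem_list Problem-list rows (`patient_id`, `condition`, `source`).
#' @param acr `NULL` or data frame `patient_id`, `acr` (mg/g) from the study
#'   panel, for the albuminuria denominator.
#' @param period Length-2 date vector (start, end) for the initiation
#'   measure; also used as the med-activity reference (`period[1]`).
#' @param age_ref_date Reference date for age; default `period[1]`.
#' @return Data frame: `measure`, `arm` (including `"pooled"`), `numerator`,
#'   `denominator`, `percent`.
#' @export
process_outcomes <- function(patients, medications, problem_list, acr = NULL,
                             period, age_ref_date = period[1]) {
  period <- as.Date(period)
  age_ref_date <- as.Date(age_ref_date)
  active_at <- function(cls, when) {
    m <- medications[medications$med_class == cls, , drop = FALSE]
    m <- m[as.Date(m$active_from) <= when &
             (is.na(m$active_to) | as.Date(m$active_to) > when), , drop = FALSE]
    unique(m$patient_id)
  }
  ckd_any <- unique(problem_list$patient_id[problem_list$condition == "ckd"])
  ckd_pl <- unique(problem_list$patient_id[problem_list$condition == "ckd" &
                                             problem_list$source == "problem_list"])
  albuminuric <- if (is.null(acr)) character() else
    unique(acr$patient_id[!is.na(acr$acr) & acr$acr > 30])
  age <- age_at(patients$birth_date, age_ref_date)
  aged50 <- patients$patient_id[age >= 50]
  statin_now <- active_at("statin", period[1])
  statin_new <- unique(medications$patient_id[
    medications$med_class == "statin" &
      as.Date(medications$active_from) >= period[1] &
      as.Date(medications$active_from) <= period[2]])
  statin_naive <- setdiff(patients$patient_id, statin_now)
  measures <- list(
    ckd_recognized = list(num = ckd_any, den = patients$patient_id),
    ckd_on_problem_list = list(num = ckd_pl, den = patients$patient_id),
    acei_arb_for_albuminuria = list(num = active_at("acei_arb", period[1]),
                                    den = albuminuric),
    statin_age50plus = list(num = statin_now, den = aged50),
    statin_initiated_in_period = list(num = statin_new, den = statin_naive)
  )
  arms <- c(sort(unique(patients$arm)), "pooled")
  out <- list()
  for (ms in names(measures)) {
    den_ids <- intersect(measures[[ms]]$den, patients$patient_id)
    num_ids <- intersect(measures[[ms]]$num, den_ids)
    for (a in arms) {
      ids <- if (a == "pooled") patients$patient_id else
        patients$patient_id[patients$arm == a]
      num <- length(intersect(num_ids, ids))
      den <- length(intersect(den_ids, ids))
      out[[length(out) + 1L]] <- data.frame(
        measure = ms, arm = a, numerator = num, denominator = den,
        percent = pct1(num, den), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
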