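# Patient-eligibility algorithm and exclusion cascade. Inclusion criteria:
# age 18-80 at the index date; preferred language English/Spanish/Chinese;
# two outpatient eGFR_Cr values of 30-59 mL/min/1.73m^2 at least 90 days
# apart, the later within the 12 months before the index date; and a PCP
# visit within the past 18 months. Automated exclusions: deceased, ESRD,
# nephrology engagement (>= 2 visits in 12 months), transplant, dementia.
# Manual exclusions and opt-outs arrive as input tables, never inferred.
#
# Dialect (fixed so results are bit-stable): the 30-59 range is inclusive on
# both ends; "at least 90 days apart" means a date difference >= 90 calendar
# days; "within the 12 months" means within the 365 days strictly before the
# index date; "past 18 months" is 548 days. eGFR is recomputed from stored
# creatinine results via the CKD-EPI 2009 equation — a stored eGFR column is
# never trusted.

ELIGIBLE_LANGUAGES <- c("English", "Spanish", "Chinese")

REASON_CODES <- c("age_range", "language", "insufficient_egfr_pair",
                  "no_recent_egfr", "no_recent_pcp_visit", "deceased", "esrd",
                  "nephrology_engaged", "transplant", "dementia")

#' Find a qualifying eGFR pair
#'
#' Searches an outpatient eGFR history for two values in \[30, 59\]
#' mL/min/1.73m^2 whose dates differ by at least 90 days, with the later of
#' the two inside the 365 days strictly before `index_date`. When several
#' pairs qualify, the returned evidence is the pair with the most recent
#' later date, ties broken by the earlier first date — a deterministic
#' choice.
#'
#' @param egfr_history Data frame with columns `value` (mL/min/1.73m^2) and
#'   `date`.
#' @param index_date Reference date.
#' @param range Inclusive eGFR window; default `c(30, 59)`.
#' @param min_gap_days Minimum date separation; default 90.
#' @param recency_days Window before `index_date` the later value must fall
#'   in; default 365.
#' @return A list with `value1`, `date1`, `value2`, `date2` (`date1 <
#'   date2`), or `NULL` when no pair qualifies.
#' @export
find_qualifying_egfr_pair <- function(egfr_history, index_date,
                                      range = c(30, 59),
                                      min_gap_days = 90,
                                      recency_days = 365) {
  index_date <- as.Date(index_date)
  if (is.null(egfr_history) || nrow(egfr_history) == 0) return(NULL)
  h <- egfr_history[!is.na(egfr_history$value) & !is.na(egfr_history$date), ]
  h$date <- as.Date(h$date)
  h <- h[h$date < index_date, ]
  h <- h[h$value >= range[1] & h$value <= range[2], ]
  if (nrow(h) < 2) return(NULL)
  h <- h[order(h$date), ]
  recent_lo <- index_date - recency_days
  # candidate later members, most recent first
  for (j in rev(seq_len(nrow(h)))) {
    if (h$date[j] < recent_lo) break
    earlier <- which(h$date <= h$date[j] - min_gap_days)
    if (length(earlier)) {
      i <- earlier[1] # earliest qualifying first date
      return(list(value1 = h$value[i], date1 = h$date[i],
                  value2 = h$value[j], date2 = h$date[j]))
    }
  }
  NULL
}

#' Automated EHR-based exclusions
#'
#' Emits every triggered automated exclusion code for one patient:
#' `deceased`, `esrd`, `transplant`, `dementia` (from the patient record /
#' problem list), and `nephrology_engaged` when the patient had 2 or more
#' nephrology visits within the 365 days before `index_date`.
#'
#' @param patient One row of the patients table.
#' @param encounters Encounter rows for this patient.
#' @param problem_list Problem-list rows for this patient.
#' @param index_date Reference date.
#' @return Character vector of triggered codes (possibly empty).
#' @export
apply_automated_exclusions <- function(patient, encounters, problem_list,
                                       index_date) {
  index_date <- as.Date(index_date)
  codes <- character()
  if (isTRUE(patient$deceased)) codes <- c(codes, "deceased")
  conds <- if (!is.null(problem_list) && nrow(problem_list)) {
    unique(problem_list$condition)
  } else character()
  if ("esrd" %in% conds) codes <- c(codes, "esrd")
  n_neph <- 0L
  if (!is.null(encounters) && nrow(encounters)) {
    d <- as.Date(encounters$occurred_at)
    n_neph <- sum(encounters$type == "nephrology_visit" &
                    d >= index_date - 365 & d < index_date)
  }
  if (n_neph >= 2) codes <- c(codes, "nephrology_engaged")
  if ("transplant" %in% conds) codes <- c(codes, "transplant")
  if ("dementia" %in% conds) codes <- c(codes, "dementia")
  codes
}

#' Build the trial cohort from EHR tables
#'
#' Applies, in order: the four inclusion criteria (age range, language,
#' qualifying eGFR pair, recent PCP visit), the automated exclusions, the
#' manual-exclusion flag table, and opt-outs. Every triggered reason code is
#' retained per patient; for the funnel summary each patient is counted once
#' in the bucket of the first rule that removed them.
#'
#' @param ehr An `ehr_dataset` (or list of equally named tables).
#' @param index_date Reference date; defaults to the generator config's.
#' @param manual_exclusions `NULL` or a data frame with columns `patient_id`
#'   and `subcode` (e.g. pregnancy, limited life expectancy, PCP discretion).
#' @param opt_outs `NULL` or a character vector of patient ids.
#' @param race_coefficient_enabled Passed to [egfr_creatinine()] when
#'   recomputing eGFR from creatinine labs.
#' @return A list of class `cohort_selection` with `decisions` (one row per
#'   patient: `eligible`, pipe-delimited `reason_codes`, evidence pair) and
#'   `funnel` (stage counts; see [selection_funnel()]).
#' @export
build_cohort <- function(ehr, index_date = NULL, manual_exclusions = NULL,
                         opt_outs = NULL, race_coefficient_enabled = FALSE) {
  for (tab in c("patients", "labs", "encounters", "problem_list")) {
    if (is.null(ehr[[tab]])) {
      stop(sprintf("EHR dataset is missing the '%s' table", tab), call. = FALSE)
    }
  }
  if (is.null(index_date)) {
    index_date <- ehr$config$index_date
    if (is.null(index_date)) stop("index_date is required", call. = FALSE)
  }
  index_date <- as.Date(index_date)
  pats <- ehr$patients
  enc_split <- split(ehr$encounters, ehr$encounters$patient_id)
  crea <- ehr$labs[ehr$labs$analyte == "serum_creatinine", ]
  crea_split <- split(crea, crea$patient_id)
  pl_split <- split(ehr$problem_list, ehr$problem_list$patient_id)
  manual_ids <- if (is.null(manual_exclusions)) character() else manual_exclusions$patient_id

  n <- nrow(pats)
  eligible <- logical(n)
  reasons <- character(n)
  ev <- data.frame(egfr1 = rep(NA_real_, n), date1 = as.Date(rep(NA, n)),
                   egfr2 = NA_real_, date2 = as.Date(rep(NA, n)))
  for (i in seq_len(n)) {
    p <- pats[i, ]
    codes <- character()
    age <- age_at(p$birth_date, index_date)
    if (age < 18 || age > 80) codes <- c(codes, "age_range")
    if (!(p$preferred_language %in% ELIGIBLE_LANGUAGES)) {
      codes <- c(codes, "language")
    }
    labs_i <- crea_split[[p$patient_id]]
    pair <- NULL
    if (!is.null(labs_i)) {
      out_labs <- labs_i[labs_i$setting == "outpatient", ]
      if (nrow(out_labs)) {
        hist <- data.frame(
          value = egfr_creatinine(out_labs$value,
                                  pmax(age_at(p$birth_date, out_labs$collected_at), 18),
                                  p$sex, race_coefficient_enabled),
          date = as.Date(out_labs$collected_at))
        pair <- find_qualifying_egfr_pair(hist, index_date)
        if (is.null(pair)) {
          # distinguish "no such pair at all" from "pair exists but stale"
          stale <- find_qualifying_egfr_pair(hist, index_date,
                                             recency_days = 100000L)
          codes <- c(codes, if (is.null(stale)) "insufficient_egfr_pair"
                            else "no_recent_egfr")
        }
      } else {
        codes <- c(codes, "insufficient_egfr_pair")
      }
    } else {
      codes <- c(codes, "insufficient_egfr_pair")
    }
    enc_i <- enc_split[[p$patient_id]]
    recent_pcp <- !is.null(enc_i) &&
      any(enc_i$type == "pcp_visit" &
            as.Date(enc_i$occurred_at) >= index_date - 548 &
            as.Date(enc_i$occurred_at) < index_date)
    if (!recent_pcp) codes <- c(codes, "no_recent_pcp_visit")

    codes <- c(codes, apply_automated_exclusions(p, enc_i,
                                                 pl_split[[p$patient_id]],
                                                 index_date))
    if (p$patient_id %in% manual_ids) {
      sub <- manual_exclusions$subcode[manual_exclusions$patient_id == p$patient_id][1]
      codes <- c(codes, paste0("manual_exclusion:", sub))
    }
    if (p$patient_id %in% opt_outs) codes <- c(codes, "opt_out")

    eligible[i] <- length(codes) == 0
    reasons[i] <- paste(codes, collapse = "|")
    if (eligible[i] && !is.null(pair)) {
      ev$egfr1[i] <- pair$value1; ev$date1[i] <- pair$date1
      ev$egfr2[i] <- pair$value2; ev$date2[i] <- pair$date2
    }
  }
  decisions <- cbind(
    data.frame(patient_id = pats$patient_id, eligible = eligible,
               reason_codes = reasons, stringsAsFactors = FALSE),
    ev)
  structure(list(decisions = decisions, funnel = selection_funnel(decisions),
                 index_date = index_date),
            class = "cohort_selection")
}

#' Selection funnel from a decisions table
#'
#' Summarizes an eligibility decisions table into the participant-selection
#' funnel: patients screened; initially eligible (no inclusion-criterion
#' failure); removed by automated exclusions; removed by manual / clinician
#' exclusions; distributed to arms; opted out or withdrew; included. Each
#' patient lands in the bucket of the first rule (in cascade order) that
#' removed them. Also reports the automated-exclusion rate (automated
#' removals over initially eligible) and retention (included over
#' distributed) as percentages rounded to one decimal.
#'
#' @param decisions Data frame with columns `patient_id`, `eligible`,
#'   `reason_codes` (pipe-delimited, cascade order).
#' @return A list of class `selection_funnel` with the stage counts and rates.
#' @export
selection_funnel <- function(decisions) {
  first_code <- vapply(strsplit(decisions$reason_codes, "|", fixed = TRUE),
                       function(x) if (length(x)) x[1] else "", "")
  inclusion_codes <- c("age_range", "language", "insufficient_egfr_pair",
                       "no_recent_egfr", "no_recent_pcp_visit")
  automated_codes <- c("deceased", "esrd", "nephrology_engaged", "transplant",
                       "dementia")
  fails_inclusion <- first_code %in% inclusion_codes
  auto_excluded <- first_code %in% automated_codes
  manual_excluded <- startsWith(first_code, "manual_exclusion")
  opted_out <- first_code == "opt_out"
  n_screened <- nrow(decisions)
  n_initial <- sum(!fails_inclusion)
  n_auto <- sum(auto_excluded)
  n_manual <- sum(manual_excluded)
  n_distributed <- n_initial - n_auto - n_manual
  n_opt_out <- sum(opted_out)
  n_included <- sum(decisions$eligible)
  stopifnot(n_included == n_distributed - n_opt_out) # funnel conservation
  structure(list(
    n_screened = n_screened,
    n_initially_eligible = n_initial,
    n_auto_excluded = n_auto,
    n_manual_excluded = n_manual,
    n_distributed = n_distributed,
    n_opt_out = n_opt_out,
    n_included = n_included,
    auto_exclusion_rate_pct = pct1(n_auto, n_initial),
    retention_pct = pct1(n_included, n_distributed)
  ), class = "selection_funnel")
}

#' @export
print.selection_funnel <- function(x, ...) {
  cat("Participant selection funnel\n")
  cat(sprintf("  screened:            %d\n", x$n_screened))
  cat(sprintf("  initially eligible:  %d\n", x$n_initially_eligible))
  cat(sprintf("  automated exclusion: %d (%.1f%%)\n", x$n_auto_excluded,
              x$auto_exclusion_rate_pct))
  cat(sprintf("  manual exclusion:    %d\n", x$n_manual_excluded))
  cat(sprintf("  distributed to arms: %d\n", x$n_distributed))
  cat(sprintf("  opt-out/withdrawn:   %d\n", x$n_opt_out))
  cat(sprintf("  included:            %d (%.1f%% retention)\n", x$n_included,
              x$retention_pct))
  invisible(x)
}

#' @export
print.cohort_selection <- function(x, ...) {
  print(x$funnel)
  invisible(x)
}
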