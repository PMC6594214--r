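# Nephrologist weekly safety surveillance. Four rules, comparators exactly
# as specified: eGFR_Cr decline > 30% from baseline; ACR >= 1000 mg/g
# (inclusive); discordance > 30% between eGFR_Cr and eGFR_Cys on the same
# panel, relative to eGFR_Cr; and nephrology-referral non-adherence past a
# configurable lag. The discordance denominator (eGFR_Cr, the routinely
# reported value) and the adherence lag (90 days) are configurable because
# neither is pinned down by the workflow itself.

SAFETY_RULES <- c("egfr_decline_gt30pct", "acr_ge_1000",
                  "referral_nonadherence", "egfr_discordance_gt30pct")

#' Safety-review configuration
#'
#' @param decline_frac Relative eGFR_Cr decline from baseline that fires the
#'   decline rule (strict `>`); default 0.30.
#' @param acr_cutoff ACR flag cutoff, mg/g, inclusive (`>=`); default 1000.
#' @param discordance_frac Relative creatinine/cystatin eGFR discordance
#'   (strict `>`); default 0.30.
#' @param discordance_denom `"egfr_cr"` (default) or `"egfr_cys"` — the base
#'   of the discordance ratio.
#' @param referral_lag_days Days after a signed nephrology referral without
#'   a nephrology visit before the non-adherence rule fires; default 90.
#' @return A list of class `safety_config`.
#' @export
safety_config <- function(decline_frac = 0.30, acr_cutoff = 1000,
                          discordance_frac = 0.30,
                          discordance_denom = c("egfr_cr", "egfr_cys"),
                          referral_lag_days = 90L) {
  discordance_denom <- match.arg(discordance_denom)
  structure(list(decline_frac = decline_frac, acr_cutoff = acr_cutoff,
                 discordance_frac = discordance_frac,
                 discordance_denom = discordance_denom,
                 referral_lag_days = as.integer(referral_lag_days)),
            class = "safety_config")
}

#' Weekly nephrologist safety review
#'
#' Scans the week's resulted panels and the open referrals and emits one
#' flag per (patient, rule). Rules:
#' * `egfr_decline_gt30pct`: `(baseline - current) / baseline > 0.30`;
#'   skipped (and reported in the `unassessed` attribute) for patients with
#'   no baseline eGFR_Cr.
#' * `acr_ge_1000`: ACR at or above 1000 mg/g (inclusive as printed).
#' * `egfr_discordance_gt30pct`: `|eGFR_Cr - eGFR_Cys| / eGFR_Cr > 0.30` on
#'   a same-panel pair.
#' * `referral_nonadherence`: a nephrology referral signed more than
#'   `referral_lag_days` before `review_date` with no nephrology visit since.
#'
#' The function is pure: the same inputs always yield the same flags, so
#' re-running a review week cannot duplicate them.
#'
#' @param panels Data frame of results since the last review: `patient_id`,
#'   `resulted_at`, and any of `egfr_cr`, `egfr_cys`, `acr` (NA when not
#'   part of the week's results).
#' @param baselines Data frame `patient_id`, `baseline_egfr_cr` (most recent
#'   outpatient value before enrollment).
#' @param referrals `NULL` or data frame `patient_id`, `referred_at`,
#'   `followed_up_at` (`NA` until a nephrology visit happens).
#' @param review_date Date of this review.
#' @param config A [safety_config()].
#' @return Data frame of flags — `patient_id`, `rule`, `detected_at`,
#'   `value`, `reference` — with an `unassessed` attribute listing patients
#'   whose decline rule could not be evaluated.
#' @export
weekly_review <- function(panels, baselines, referrals = NULL,
                          review_date, config = safety_config()) {
  review_date <- as.Date(review_date)
  flags <- list()
  unassessed <- character()
  mk <- function(patient_id, rule, value, reference) {
    data.frame(patient_id = patient_id, rule = rule,
               detected_at = review_date, value = value,
               reference = reference, stringsAsFactors = FALSE)
  }
  if (!is.null(panels) && nrow(panels)) {
    base_map <- if (is.null(baselines)) numeric() else
      stats::setNames(baselines$baseline_egfr_cr, baselines$patient_id)
    for (i in seq_len(nrow(panels))) {
      row <- panels[i, ]
      cur <- row$egfr_cr
      if (!is.null(cur) && !is.na(cur)) {
        base <- unname(base_map[row$patient_id])
        if (length(base) == 0) base <- NA_real_
        if (is.na(base)) {
          unassessed <- c(unassessed, row$patient_id)
        } else if ((base - cur) / base > config$decline_frac) {
          flags[[length(flags) + 1L]] <-
            mk(row$patient_id, "egfr_decline_gt30pct", cur, base)
        }
      }
      if (!is.null(row$acr) && !is.na(row$acr) &&
          row$acr >= config$acr_cutoff) {
        flags[[length(flags) + 1L]] <-
          mk(row$patient_id, "acr_ge_1000", row$acr, config$acr_cutoff)
      }
      if (!is.null(cur) && !is.na(cur) &&
          !is.null(row$egfr_cys) && !is.na(row$egfr_cys)) {
        denom <- if (config$discordance_denom == "egfr_cr") cur else row$egfr_cys
        if (abs(cur - row$egfr_cys) / denom > config$discordance_frac) {
          flags[[length(flags) + 1L]] <-
            mk(row$patient_id, "egfr_discordance_gt30pct",
               abs(cur - row$egfr_cys) / denom, config$discordance_frac)
        }
      }
    }
  }
  if (!is.null(referrals) && nrow(referrals)) {
    for (i in seq_len(nrow(referrals))) {
      r <- referrals[i, ]
      overdue <- as.Date(r$referred_at) <= review_date - config$referral_lag_days
      seen <- !is.na(r$followed_up_at) &&
        as.Date(r$followed_up_at) <= review_date
      if (overdue && !seen) {
        flags[[length(flags) + 1L]] <-
          mk(r$patient_id, "referral_nonadherence",
             as.numeric(review_date - as.Date(r$referred_at)),
             config$referral_lag_days)
      }
    }
  }
  out <- if (length(flags)) do.call(rbind, flags) else
    data.frame(patient_id = character(), rule = character(),
               detected_at = as.Date(character()), value = numeric(),
               reference = numeric(), stringsAsFactors = FALSE)
  out <- unique(out) # one flag per (patient, rule, review week)
  rownames(out) <- NULL
  structure(out, unassessed = unique(unassessed))
}
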