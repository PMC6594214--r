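# Shared test fixtures, all built in code.

small_ehr <- function(seed = 42, n_providers = 20, patients_per_provider = 8,
                      ...) {
  generate_population(generator_config(n_providers = n_providers,
                                       patients_per_provider = patients_per_provider,
                                       seed = seed, ...))
}

# An eGFR history data frame from (value, days-before-index) pairs.
egfr_hist <- function(values, days_before, index = as.Date("2017-10-04")) {
  data.frame(value = values, date = index - days_before)
}

# A quick encounter table for BP-outcome tests.
bp_encounters <- function(days, sbp, dbp, type = "pcp_visit",
                          origin = as.Date("2017-10-04")) {
  data.frame(encounter_id = sprintf("E%03d", seq_along(days)),
             patient_id = "pt1", provider_id = "P001",
             occurred_at = origin + days, type = type,
             systolic_bp = sbp, diastolic_bp = dbp,
             stringsAsFactors = FALSE)
}

# Random patient state for property tests over the rules engine.
random_state <- function() {
  meds <- sample(c("statin", "acei_arb", "thiazide_diuretic", "loop_diuretic",
                   "beta_blocker", "ccb", "nsaid"),
                 sample(0:5, 1))
  patient_state(
    age = sample(30:90, 1),
    sex = sample(c("female", "male"), 1),
    panel = list(egfr_cys = runif(1, 5, 120), acr = exp(runif(1, log(1), log(3000)))),
    potassium = if (runif(1) < 0.15) NA_real_ else runif(1, 3.2, 6.8),
    recent_sbp = runif(1, 100, 190),
    active_med_classes = meds,
    preferred_language = sample(c("English", "Spanish", "Chinese"), 1),
    kfre = runif(1, 0, 0.25)
  )
}
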