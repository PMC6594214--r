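# Synthetic EHR generator. Produces the linked tables every downstream stage
# consumes (patients, providers, labs, encounters, medications, problem list)
# plus a ground-truth sidecar used only by tests, never by the engine.
#
# The defaults emulate the primary-care panel the trial drew from: 81
# providers (47 attending / 31 resident / 3 NP), patients aged mostly 30-80
# with mean ~70, hypertension 72%, diabetes 38%, statin 67%, ACEi/ARB 61%,
# systolic BP with a between-provider intraclass correlation of 0.025 and
# total SD 5 mmHg around a mean of 128 mmHg.

#' Configuration for the synthetic EHR generator
#'
#' @param n_providers Number of primary-care providers (clusters).
#' @param patients_per_provider Expected panel size; patients are assigned to
#'   providers uniformly at random, so realized panel sizes vary.
#' @param frac_eligible Fraction of patients generated to satisfy every
#'   trial inclusion criterion and no exclusion; each remaining patient
#'   violates exactly one criterion, chosen uniformly, so every exclusion
#'   path is exercised.
#' @param index_date Reference date for eligibility arithmetic.
#' @param role_shares Named shares for provider roles
#'   (attending/resident/nurse_practitioner); realized counts follow
#'   largest-remainder quotas, so `n_providers = 81` yields exactly 47/31/3.
#' @param sex_female Probability a patient is female.
#' @param age_mean,age_sd Age distribution (years) for in-range patients,
#'   truncated to \[30, 80\].
#' @param language_shares,race_shares,insurance_shares Named categorical shares.
#' @param comorbidity_prev Named prevalences for the comorbidity flags.
#' @param med_prev Named prevalences for active medication classes.
#' @param ckd_problem_list_prev,ckd_any_dx_prev Prevalence of a CKD entry on
#'   the problem list, and of CKD on problem list *or* visit diagnosis.
#' @param bp_mean,bp_sd Systolic BP grand mean and total SD (mmHg).
#' @param bp_icc Between-provider intraclass correlation of systolic BP,
#'   in \[0, 1).
#' @param dbp_mean,dbp_sd Diastolic BP mean and SD (mmHg).
#' @param visits_per_year Expected ambulatory PCP visit rate after the index
#'   date (the trial horizon).
#' @param horizon_days Length of the post-index observation window.
#' @param seed Integer seed; the full dataset is a deterministic function of
#'   the configuration including the seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_providers = 81,
                             patients_per_provider = 12,
                             frac_eligible = 0.6,
                             index_date = as.Date("2017-10-04"),
                             role_shares = c(attending = 47, resident = 31,
                                             nurse_practitioner = 3) / 81,
                             sex_female = 0.45,
                             age_mean = 70.3, age_sd = 8.9,
                             language_shares = c(English = 0.90, Chinese = 0.07,
                                                 Spanish = 0.03),
                             race_shares = c(White = 0.53, Asian = 0.23,
                                             Black = 0.13, Hispanic = 0.07,
                                             Other = 0.04),
                             insurance_shares = c(Private = 0.28, Medicare = 0.41,
                                                  Medicaid = 0.31),
                             comorbidity_prev = c(cerebrovascular = 0.07,
                                                  chf = 0.08, cad = 0.18,
                                                  diabetes = 0.38,
                                                  hyperlipidemia = 0.58,
                                                  hypertension = 0.72),
                             med_prev = c(statin = 0.67, acei_arb = 0.61,
                                          thiazide_diuretic = 0.25,
                                          loop_diuretic = 0.13,
                                          beta_blocker = 0.30, ccb = 0.30,
                                          nsaid = 0.10),
                             ckd_problem_list_prev = 0.12,
                             ckd_any_dx_prev = 0.47,
                             bp_mean = 128, bp_sd = 5, bp_icc = 0.025,
                             dbp_mean = 68, dbp_sd = 6,
                             visits_per_year = 3,
                             horizon_days = 365,
                             seed = 1L) {
  cfg <- list(
    n_providers = n_providers, patients_per_provider = patients_per_provider,
    frac_eligible = frac_eligible, index_date = as.Date(index_date),
    role_shares = role_shares, sex_female = sex_female,
    age_mean = age_mean, age_sd = age_sd,
    language_shares = language_shares, race_shares = race_shares,
    insurance_shares = insurance_shares,
    comorbidity_prev = comorbidity_prev, med_prev = med_prev,
    ckd_problem_list_prev = ckd_problem_list_prev,
    ckd_any_dx_prev = ckd_any_dx_prev,
    bp_mean = bp_mean, bp_sd = bp_sd, bp_icc = bp_icc,
    dbp_mean = dbp_mean, dbp_sd = dbp_sd,
    visits_per_year = visits_per_year, horizon_days = horizon_days,
    seed = as.integer(seed)
  )
  check_that(is_count(cfg$n_providers), "n_providers", "must be a positive integer")
  check_that(is_count(cfg$patients_per_provider), "patients_per_provider",
             "must be a positive integer")
  check_that(is_prob(cfg$frac_eligible), "frac_eligible", "must be in [0,1]")
  check_that(is.numeric(cfg$bp_icc) && cfg$bp_icc >= 0 && cfg$bp_icc < 1,
             "bp_icc", "intraclass correlation must be in [0,1)")
  check_that(is.numeric(cfg$bp_sd) && cfg$bp_sd >= 0, "bp_sd", "must be nonnegative")
  check_that(all(cfg$comorbidity_prev >= 0 & cfg$comorbidity_prev <= 1),
             "comorbidity_prev", "all prevalences must be in [0,1]")
  check_that(all(cfg$med_prev >= 0 & cfg$med_prev <= 1),
             "med_prev", "all prevalences must be in [0,1]")
  check_that(is.numeric(cfg$visits_per_year) && cfg$visits_per_year >= 0,
             "visits_per_year", "must be nonnegative")
  check_that(!is.na(cfg$seed), "seed", "must be an integer")
  structure(cfg, class = "generator_config")
}

# Largest-remainder apportionment of n units to named shares.
quota_counts <- function(n, shares) {
  q <- n * shares / sum(shares)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    add <- order(q - k, decreasing = TRUE)[seq_len(rem)]
    k[add] <- k[add] + 1
  }
  k
}

sample_cat <- function(n, shares) {
  sample(names(shares), n, replace = TRUE, prob = shares)
}

# Violation categories (one per excluded patient) and the reason code the
# selection algorithm is expected to emit for each.
violation_catalog <- function() {
  c(age_range = "age_range",
    language = "language",
    egfr_out_of_range = "insufficient_egfr_pair",
    egfr_gap_too_short = "insufficient_egfr_pair",
    single_egfr = "insufficient_egfr_pair",
    no_recent_egfr = "no_recent_egfr",
    no_recent_pcp_visit = "no_recent_pcp_visit",
    deceased = "deceased",
    esrd = "esrd",
    nephrology_engaged = "nephrology_engaged",
    transplant = "transplant",
    dementia = "dementia")
}

#' Generate a synthetic primary-care EHR dataset
#'
#' Builds linked tables — `patients`, `providers`, `labs`, `encounters`,
#' `medications`, `problem_list` — plus a `ground_truth` sidecar carrying each
#' patient's true eligibility label, the single criterion violated (if any),
#' and latent cystatin-C / ACR values with the implied risk tier. The sidecar
#' exists for test oracles; the selection and decision-support code never
#' reads it.
#'
#' Creatinine labs are planted by inverting the CKD-EPI 2009 equation, so a
#' patient generated as eligible has, by construction, two outpatient eGFR
#' values in 30-59 mL/min/1.73m^2 at least 90 days apart with the later one
#' inside the 12 months before the index date. Each ineligible patient fails
#' exactly one criterion (see `frac_eligible`).
#'
#' Systolic BP at every ambulatory visit is grand mean + a Gaussian provider
#' effect with variance `bp_icc * bp_sd^2` + a Gaussian residual with
#' variance `(1 - bp_icc) * bp_sd^2`.
#'
#' @param config A [generator_config()].
#' @return An object of class `ehr_dataset`: a named list of data frames plus
#'   the generating config.
#' @export
generate_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  index <- cfg$index_date
  n_prov <- cfg$n_providers
  providers <- data.frame(
    provider_id = sprintf("P%03d", seq_len(n_prov)),
    role = sample(rep(names(cfg$role_shares), quota_counts(n_prov, cfg$role_shares))),
    stringsAsFactors = FALSE
  )
  provider_effect <- stats::rnorm(n_prov, 0, sqrt(cfg$bp_icc) * cfg$bp_sd)
  names(provider_effect) <- providers$provider_id

  n_pat <- n_prov * cfg$patients_per_provider
  cats <- ifelse(stats::runif(n_pat) < cfg$frac_eligible, "eligible",
                 sample(names(violation_catalog()), n_pat, replace = TRUE))

  age <- pmin(pmax(round(stats::rnorm(n_pat, cfg$age_mean, cfg$age_sd)), 30), 80)
  age[cats == "age_range"] <- sample(82:92, sum(cats == "age_range"), replace = TRUE)
  birth_offset <- sample(30:300, n_pat, replace = TRUE)
  birth_date <- index - round(age * 365.25) - birth_offset

  language <- sample_cat(n_pat, cfg$language_shares)
  language[cats == "language"] <- "Other"
  sex <- ifelse(stats::runif(n_pat) < cfg$sex_female, "female", "male")

  patients <- data.frame(
    patient_id = sprintf("PT%05d", seq_len(n_pat)),
    provider_id = sample(providers$provider_id, n_pat, replace = TRUE),
    birth_date = birth_date,
    sex = sex,
    race_ethnicity = sample_cat(n_pat, cfg$race_shares),
    preferred_language = language,
    insurance = sample_cat(n_pat, cfg$insurance_shares),
    deceased = cats == "deceased",
    stringsAsFactors = FALSE
  )
  for (cm in names(cfg$comorbidity_prev)) {
    patients[[cm]] <- stats::runif(n_pat) < cfg$comorbidity_prev[[cm]]
  }

  # --- creatinine labs, planted per category -------------------------------
  lab_rows <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    cat_i <- cats[i]
    a <- age[i]; s <- sex[i]
    mk <- function(days_before, target, setting = "outpatient") {
      d <- index - days_before
      data.frame(patient_id = patients$patient_id[i],
                 analyte = "serum_creatinine",
                 value = round(invert_egfr_creatinine(target, age_at(birth_date[i], d), s), 3),
                 collected_at = d, setting = setting, stringsAsFactors = FALSE)
    }
    rows <- switch(cat_i,
      egfr_out_of_range = {
        d2 <- sample(20:340, 1); gap <- sample(100:360, 1)
        rbind(mk(d2 + gap, stats::runif(1, 63, 85)), mk(d2, stats::runif(1, 63, 85)))
      },
      egfr_gap_too_short = {
        d2 <- sample(20:200, 1); gap <- sample(10:80, 1)
        rbind(mk(d2 + gap, stats::runif(1, 33, 56)), mk(d2, stats::runif(1, 33, 56)))
      },
      single_egfr = mk(sample(20:340, 1), stats::runif(1, 33, 56)),
      no_recent_egfr = {
        d2 <- sample(400:600, 1); gap <- sample(100:300, 1)
        rbind(mk(d2 + gap, stats::runif(1, 33, 56)),
              mk(d2, stats::runif(1, 33, 56)),
              # recent but inpatient: must not rescue eligibility
              mk(sample(20:90, 1), stats::runif(1, 33, 56), setting = "inpatient"))
      },
      { # eligible pattern (also used by every non-lab violation category)
        d2 <- sample(20:340, 1); gap <- sample(100:360, 1)
        rbind(mk(d2 + gap, stats::runif(1, 33, 56)), mk(d2, stats::runif(1, 33, 56)))
      })
    lab_rows[[i]] <- rows
  }
  labs <- do.call(rbind, lab_rows)

  # potassium labs near the index date for most patients
  has_k <- stats::runif(n_pat) < 0.8
  if (any(has_k)) {
    k_high <- stats::runif(sum(has_k)) < 0.05
    labs <- rbind(labs, data.frame(
      patient_id = patients$patient_id[has_k],
      analyte = "potassium",
      value = round(ifelse(k_high, stats::runif(sum(has_k), 5.6, 6.2),
                           stats::runif(sum(has_k), 3.5, 5.3)), 1),
      collected_at = index - sample(5:120, sum(has_k), replace = TRUE),
      setting = "outpatient", stringsAsFactors = FALSE))
  }

  # --- encounters ----------------------------------------------------------
  enc_rows <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    pid <- patients$patient_id[i]
    prov <- patients$provider_id[i]
    eff <- provider_effect[[prov]]
    cat_i <- cats[i]
    pre_days <- if (cat_i == "no_recent_pcp_visit") {
      sample(600:900, 1 + stats::rpois(1, 1))
    } else {
      sample(10:500, 1 + stats::rpois(1, 1.5), replace = FALSE)
    }
    dates <- index - pre_days
    types <- rep("pcp_visit", length(dates))
    if (cat_i == "nephrology_engaged") {
      nd <- index - sample(30:300, 2 + stats::rbinom(1, 1, 0.5))
      dates <- c(dates, nd); types <- c(types, rep("nephrology_visit", length(nd)))
    } else if (cat_i == "eligible" && stats::runif(1) < 0.1) {
      dates <- c(dates, index - sample(30:300, 1)) # single visit: below threshold
      types <- c(types, "nephrology_visit")
    }
    n_post <- stats::rpois(1, cfg$visits_per_year * cfg$horizon_days / 365)
    if (n_post > 0) {
      dates <- c(dates, index + sample.int(cfg$horizon_days, n_post))
      types <- c(types, rep("pcp_visit", n_post))
    }
    if (stats::runif(1) < 0.2) {
      dates <- c(dates, index + sample.int(cfg$horizon_days, 1))
      types <- c(types, "non_pcp_visit")
    }
    bp <- generate_bp_series(dates, eff, cfg)
    enc_rows[[i]] <- data.frame(
      patient_id = pid,
      provider_id = ifelse(types == "pcp_visit", prov,
                           sample(providers$provider_id, length(dates), replace = TRUE)),
      occurred_at = dates, type = types,
      systolic_bp = bp$sbp, diastolic_bp = bp$dbp,
      stringsAsFactors = FALSE)
  }
  encounters <- do.call(rbind, enc_rows)
  encounters$encounter_id <- sprintf("E%06d", seq_len(nrow(encounters)))
  encounters <- encounters[order(encounters$patient_id, encounters$occurred_at,
                                 encounters$encounter_id), ]
  rownames(encounters) <- NULL

  # --- medications ---------------------------------------------------------
  med_rows <- list()
  for (cls in names(cfg$med_prev)) {
    on <- stats::runif(n_pat) < cfg$med_prev[[cls]]
    if (any(on)) {
      med_rows[[cls]] <- data.frame(
        patient_id = patients$patient_id[on],
        med_class = cls,
        active_from = index - sample(100:1000, sum(on), replace = TRUE),
        active_to = as.Date(NA), stringsAsFactors = FALSE)
    }
  }
  medications <- do.call(rbind, med_rows)
  rownames(medications) <- NULL

  # --- problem list --------------------------------------------------------
  pl_rows <- list()
  for (cond in c("esrd", "transplant", "dementia")) {
    who <- cats == cond
    if (any(who)) {
      pl_rows[[cond]] <- data.frame(
        patient_id = patients$patient_id[who], condition = cond,
        source = "problem_list",
        recorded_at = index - sample(100:800, sum(who), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  on_pl <- stats::runif(n_pat) < cfg$ckd_problem_list_prev
  extra <- !on_pl & stats::runif(n_pat) <
    (cfg$ckd_any_dx_prev - cfg$ckd_problem_list_prev) / (1 - cfg$ckd_problem_list_prev)
  if (any(on_pl)) {
    pl_rows$ckd_pl <- data.frame(
      patient_id = patients$patient_id[on_pl], condition = "ckd",
      source = "problem_list",
      recorded_at = index - sample(30:800, sum(on_pl), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  if (any(extra)) {
    pl_rows$ckd_dx <- data.frame(
      patient_id = patients$patient_id[extra], condition = "ckd",
      source = "visit_diagnosis",
      recorded_at = index - sample(30:800, sum(extra), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  problem_list <- do.call(rbind, pl_rows)
  rownames(problem_list) <- NULL

  # --- ground truth sidecar ------------------------------------------------
  target_cys <- stats::runif(n_pat, 30, 90)
  scys <- round(invert_egfr_cystatin(target_cys, age, sex), 3)
  egfr_cys <- egfr_cystatin(scys, age, sex)
  acr <- round(stats::rlnorm(n_pat, log(30), 1.2), 1)
  acr[acr <= 0.1] <- 0.1
  ground_truth <- data.frame(
    patient_id = patients$patient_id,
    category = cats,
    true_eligible = cats == "eligible",
    true_reason = ifelse(cats == "eligible", "",
                         unname(violation_catalog()[cats])),
    true_scys = scys,
    true_acr = acr,
    true_egfr_cys = egfr_cys,
    true_risk_tier = ifelse(egfr_cys < 60 | acr > 30, "high", "low"),
    provider_effect = unname(provider_effect[patients$provider_id]),
    stringsAsFactors = FALSE
  )

  structure(
    list(patients = patients, providers = providers, labs = labs,
         encounters = encounters, medications = medications,
         problem_list = problem_list, ground_truth = ground_truth,
         config = cfg),
    class = "ehr_dataset"
  )
}

#' Generate a clustered blood-pressure series
#'
#' One measurement per supplied date: systolic BP = grand mean + the given
#' provider random effect + an independent Gaussian residual with variance
#' `(1 - bp_icc) * bp_sd^2`, so that across providers (whose effects carry
#' variance `bp_icc * bp_sd^2`) the total variance is `bp_sd^2` and the
#' intraclass correlation is `bp_icc`. Diastolic BP is generated around
#' `dbp_mean` and clamped below systolic.
#'
#' @param dates Vector of measurement dates (only its length is used).
#' @param provider_effect The provider's random effect, mmHg.
#' @param config A [generator_config()].
#' @return Data frame with columns `date`, `sbp`, `dbp`.
#' @export
generate_bp_series <- function(dates, provider_effect, config = generator_config()) {
  n <- length(dates)
  resid_sd <- sqrt(1 - config$bp_icc) * config$bp_sd
  sbp <- round(config$bp_mean + provider_effect + stats::rnorm(n, 0, resid_sd), 1)
  dbp <- round(config$dbp_mean + stats::rnorm(n, 0, config$dbp_sd), 1)
  dbp <- pmin(dbp, sbp - 10)
  data.frame(date = as.Date(dates), sbp = sbp, dbp = dbp)
}

# Inverse of the CKD-EPI 2012 cystatin-C equation (generator internal).
invert_egfr_cystatin <- function(target, age, sex) {
  sex <- match_sex(sex)
  female <- sex == "female"
  base <- 133 * 0.996^age * ifelse(female, 0.932, 1) # value at scys == 0.8
  ratio <- target / base
  ifelse(ratio >= 1, 0.8 * ratio^(1 / -0.499), 0.8 * ratio^(-1 / 1.328))
}

#' Method-of-moments (one-way ANOVA) intraclass correlation
#'
#' Estimates the ICC of `values` clustered by `cluster` from the between- and
#' within-cluster mean squares, using the average-cluster-size correction
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)` for unbalanced clusters:
#' `icc = (MSB - MSW) / (MSB + (n0 - 1) * MSW)`.
#'
#' @param values Numeric outcome vector.
#' @param cluster Cluster labels, same length.
#' @return The ICC estimate (can be slightly negative by sampling noise).
#' @export
icc_anova <- function(values, cluster) {
  cluster <- factor(cluster)
  check_that(length(values) == length(cluster), "cluster",
             "must match the length of values")
  check_that(nlevels(cluster) >= 2, "cluster", "need at least 2 clusters")
  n_i <- tabulate(cluster)
  N <- length(values)
  k <- nlevels(cluster)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  fit <- stats::aov(values ~ cluster)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  (msb - msw) / (msb + (n0 - 1) * msw)
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("Synthetic EHR dataset\n")
  cat(sprintf("  providers:  %d\n", nrow(x$providers)))
  cat(sprintf("  patients:   %d (%d generated eligible)\n",
              nrow(x$patients), sum(x$ground_truth$true_eligible)))
  cat(sprintf("  labs:       %d rows\n", nrow(x$labs)))
  cat(sprintf("  encounters: %d rows\n", nrow(x$encounters)))
  cat(sprintf("  index date: %s\n", format(x$config$index_date)))
  invisible(x)
}

#' Write / read an EHR dataset as delimited text tables
#'
#' Tables are written as RFC-4180 CSV with ISO-8601 dates: `patients.csv`,
#' `providers.csv`, `labs.csv`, `encounters.csv`, `medications.csv`,
#' `problem_list.csv`, and the test-only `ground_truth.csv` sidecar.
#'
#' @param ehr An `ehr_dataset`.
#' @param dir Directory to write into (created if missing).
#' @return `write_ehr` returns `dir` invisibly; `read_ehr` returns an
#'   `ehr_dataset` (without the generating config).
#' @export
write_ehr <- function(ehr, dir) {
  stopifnot(inherits(ehr, "ehr_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("patients", "providers", "labs", "encounters", "medications",
                "problem_list", "ground_truth")) {
    utils::write.csv(ehr[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_ehr
#' @export
read_ehr <- function(dir) {
  rd <- function(name, date_cols) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("missing EHR table: %s", path), call. = FALSE)
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (dc in intersect(date_cols, names(df))) df[[dc]] <- as.Date(df[[dc]])
    df
  }
  out <- list(
    patients = rd("patients", "birth_date"),
    providers = rd("providers", character()),
    labs = rd("labs", "collected_at"),
    encounters = rd("encounters", "occurred_at"),
    medications = rd("medications", c("active_from", "active_to")),
    problem_list = rd("problem_list", "recorded_at")
  )
  gt <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt)) out$ground_truth <- rd("ground_truth", character())
  structure(out, class = "ehr_dataset")
}
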