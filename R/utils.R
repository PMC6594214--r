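# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Validation error that names the offending field, so misconfiguration is
# diagnosable from the message alone.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1

# Age in whole years attained at `at` (calendar convention, day granularity).
age_at <- function(birth_date, at) {
  floor(as.numeric(as.Date(at) - as.Date(birth_date)) / 365.25)
}

# Proportion as a percentage rounded to one decimal, NA on a zero denominator.
pct1 <- function(num, den) {
  ifelse(den > 0, round(100 * num / den, 1), NA_real_)
}
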