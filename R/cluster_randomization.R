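# Provider-level randomization balanced on panel size: providers are sorted
# by eligible-panel size (descending, ties broken by provider id), cut into
# consecutive blocks of n_arms, and arm labels are randomly permuted within
# each block. With similar sizes inside a block, this balances both provider
# counts (exactly, up to the final short block) and patient totals per arm.

#' Randomize providers to arms in panel-size-sorted blocks
#'
#' @param providers Data frame with columns `provider_id` and `panel_size`
#'   (number of eligible patients in the panel).
#' @param n_arms Number of arms; default 3.
#' @param arms Arm labels, length `n_arms`.
#' @param seed Integer seed; the assignment is deterministic given the seed
#'   and the provider set (input row order is irrelevant — sorting is
#'   canonical).
#' @return Data frame with `provider_id`, `panel_size`, `block_index`, `arm`.
#' @export
randomize_providers <- function(providers, n_arms = 3,
                                arms = c("usual_care", "ecdss", "ecdss_plus"),
                                seed = 1L) {
  check_that(is_count(n_arms) && n_arms >= 2, "n_arms", "need at least 2 arms")
  check_that(length(arms) == n_arms, "arms", "must supply one label per arm")
  check_that(all(c("provider_id", "panel_size") %in% names(providers)),
             "providers", "needs provider_id and panel_size columns")
  check_that(all(providers$panel_size >= 0), "panel_size", "must be nonnegative")
  check_that(!anyDuplicated(providers$provider_id), "provider_id", "must be unique")
  if (nrow(providers) < n_arms) {
    stop(sprintf("need at least %d providers for %d arms", n_arms, n_arms),
         call. = FALSE)
  }
  ord <- order(-providers$panel_size, providers$provider_id)
  sorted <- providers[ord, c("provider_id", "panel_size")]
  n <- nrow(sorted)
  sorted$block_index <- (seq_len(n) - 1L) %/% n_arms + 1L
  sorted$arm <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), sorted$block_index), function(idx) {
      sample(arms)[seq_along(idx)]
    }), use.names = FALSE)
  })
  rownames(sorted) <- NULL
  sorted
}

#' Balance report for an arm assignment
#'
#' @param assignments Output of [randomize_providers()] (or any data frame
#'   with `arm` and `panel_size` per provider).
#' @return List with `per_arm` (providers and patients per arm),
#'   `max_provider_diff`, `max_patient_diff` (largest pairwise differences),
#'   and `total_patients`.
#' @export
assignment_balance_report <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) {
    return(list(per_arm = data.frame(arm = character(), n_providers = integer(),
                                     n_patients = numeric()),
                max_provider_diff = 0L, max_patient_diff = 0,
                total_patients = 0))
  }
  per_arm <- aggregate(cbind(n_providers = rep(1L, nrow(assignments)),
                             n_patients = assignments$panel_size) ~ arm,
                       data = assignments, FUN = sum)
  list(per_arm = per_arm,
       max_provider_diff = max(per_arm$n_providers) - min(per_arm$n_providers),
       max_patient_diff = max(per_arm$n_patients) - min(per_arm$n_patients),
       total_patients = sum(assignments$panel_size))
}
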