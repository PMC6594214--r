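# Cluster-randomized sample-size machinery: the design effect
# 1 + (m - 1) * rho, the minimal detectable between-arm difference for a
# balanced two-arm comparison of cluster means, and a Monte-Carlo check of
# the same design. Quantiles default to the t distribution with 2(k - 1)
# degrees of freedom — the small-sample convention that reproduces the
# study's printed 1.27 mmHg; normal quantiles (~1.24) are available behind
# a flag.

#' Cluster-trial design parameters
#'
#' @param k Clusters (providers) per arm; >= 2.
#' @param m Patients per cluster; >= 1.
#' @param icc Intraclass correlation rho, in \[0, 1).
#' @param sd Total outcome standard deviation sigma, mmHg; > 0.
#' @param alpha Two-tailed type-I level.
#' @param power Target power.
#' @return A validated list of class `power_design`. Defaults are the study
#'   design: 23 clusters/arm, 15 patients/cluster, rho = 0.025, sigma = 5,
#'   alpha = 0.05, power = 0.80.
#' @export
power_design <- function(k = 23, m = 15, icc = 0.025, sd = 5, alpha = 0.05,
                         power = 0.80) {
  check_that(is_count(k) && k >= 2, "k", "need at least 2 clusters per arm")
  check_that(is_count(m), "m", "cluster size must be a positive integer")
  check_that(is.numeric(icc) && icc >= 0 && icc < 1, "icc", "must be in [0,1)")
  check_that(is.numeric(sd) && sd > 0, "sd", "must be positive")
  check_that(is_prob(alpha) && alpha > 0 && alpha < 1, "alpha",
             "must be in (0,1)")
  check_that(is_prob(power) && power > 0 && power < 1, "power",
             "must be in (0,1)")
  structure(list(k = k, m = m, icc = icc, sd = sd, alpha = alpha,
                 power = power), class = "power_design")
}

#' Cluster-sampling design effect
#'
#' Variance inflation `1 + (m - 1) * icc` for cluster size `m` and
#' intraclass correlation `icc`.
#'
#' @param m Cluster size (>= 1).
#' @param icc Intraclass correlation in \[0, 1).
#' @return The design-effect multiplier.
#' @examples
#' design_effect(15, 0.025) # 1.35
#' @export
design_effect <- function(m, icc) {
  check_that(all(m >= 1), "m", "cluster size must be >= 1")
  check_that(all(icc >= 0 & icc < 1), "icc", "must be in [0,1)")
  1 + (m - 1) * icc
}

#' Minimal detectable between-arm difference
#'
#' For a balanced two-arm cluster design,
#' \deqn{\delta = (t_{1-\alpha/2,\,2(k-1)} + t_{power,\,2(k-1)}) \cdot
#'   \sigma \sqrt{2\,DE / (k m)}}
#' with `DE = design_effect(m, icc)`. With `df_method = "z"` the normal
#' quantiles are used instead (the large-sample limit).
#'
#' @param design A [power_design()].
#' @param df_method `"t"` (default, df = 2(k-1)) or `"z"`.
#' @return The detectable difference, in outcome units (mmHg).
#' @examples
#' detectable_difference(power_design()) # ~1.27
#' @export
detectable_difference <- function(design = power_design(),
                                  df_method = c("t", "z")) {
  stopifnot(inherits(design, "power_design"))
  df_method <- match.arg(df_method)
  de <- design_effect(design$m, design$icc)
  mult <- if (df_method == "t") {
    df <- 2 * (design$k - 1)
    stats::qt(1 - design$alpha / 2, df) + stats::qt(design$power, df)
  } else {
    stats::qnorm(1 - design$alpha / 2) + stats::qnorm(design$power)
  }
  mult * design$sd * sqrt(2 * de / (design$k * design$m))
}

#' Simulated power of the cluster design
#'
#' Monte-Carlo power of a two-sample t-test on cluster means for a balanced
#' two-arm cluster trial: each replicate draws `k` cluster means per arm
#' with variance `icc * sd^2 + (1 - icc) * sd^2 / m` (Gaussian cluster
#' effects plus the residual mean over `m` patients), shifts one arm by
#' `delta`, and tests at two-tailed level `alpha` with 2(k-1) degrees of
#' freedom.
#'
#' @param design A [power_design()].
#' @param delta True between-arm mean difference, mmHg.
#' @param n_reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @return List with `power` (rejection fraction), `mc_se`
#'   (`sqrt(p(1-p)/n_reps)`), `n_reps`, `delta`.
#' @export
simulate_power <- function(design = power_design(), delta, n_reps = 5000L,
                           seed = 1L) {
  stopifnot(inherits(design, "power_design"))
  check_that(is_count(n_reps) && n_reps >= 100, "n_reps", "need >= 100 replicates")
  k <- design$k
  s_clmean <- sqrt(design$icc * design$sd^2 + (1 - design$icc) * design$sd^2 / design$m)
  df <- 2 * (k - 1)
  crit <- stats::qt(1 - design$alpha / 2, df)
  with_seed(seed, {
    x <- matrix(stats::rnorm(k * n_reps, 0, s_clmean), nrow = k)
    y <- matrix(stats::rnorm(k * n_reps, delta, s_clmean), nrow = k)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- apply(x, 2, stats::var); vy <- apply(y, 2, stats::var)
    tstat <- (my - mx) / sqrt((vx + vy) / k) # pooled, equal n
    p_hat <- mean(abs(tstat) > crit)
    list(power = p_hat, mc_se = sqrt(p_hat * (1 - p_hat) / n_reps),
         n_reps = n_reps, delta = delta)
  })
}
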