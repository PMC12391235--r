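#' Generate a synthetic stoma-closure cohort
#'
#' Emulates the covariate structure behind the published covariate summary:
#' BMI drawn from a truncated normal (the publication reports only the
#' pooled mean, 26.41 kg/m^2; the default SD of 4 is a convention) and
#' independent Bernoulli risk-factor flags at the pooled prevalences. The
#' publication gives no covariate correlation structure, so none is
#' imposed.
#'
#' @param n number of patients.
#' @param bmi_mean,bmi_sd BMI distribution parameters (kg/m^2); `bmi_sd > 0`.
#' @param p_colostomy,p_terminal,p_parastomal flag prevalences in `[0, 1]`.
#' @param bmi_range truncation bounds for BMI.
#' @param seed optional integer seed; the generator is deterministic given
#'   a seed.
#' @return Data frame with columns `bmi`, `colostomy`, `terminal`,
#'   `parastomal_hernia`.
#' @examples
#' head(generate_cohort(5, seed = 1))
#' @export
generate_cohort <- function(n, bmi_mean = 26.41, bmi_sd = 4,
                            p_colostomy = 0.53, p_terminal = 0.51,
                            p_parastomal = 0.11,
                            bmi_range = c(15, 60), seed = NULL) {
  stopifnot(n >= 1, bmi_sd > 0)
  pr <- c(p_colostomy, p_terminal, p_parastomal)
  if (any(pr < 0 | pr > 1)) stop("flag prevalences must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  # truncated normal by inverse-CDF
  lo <- stats::pnorm(bmi_range[1], bmi_mean, bmi_sd)
  hi <- stats::pnorm(bmi_range[2], bmi_mean, bmi_sd)
  bmi <- stats::qnorm(stats::runif(n, lo, hi), bmi_mean, bmi_sd)
  data.frame(bmi = bmi,
             colostomy = stats::rbinom(n, 1, p_colostomy),
             terminal = stats::rbinom(n, 1, p_terminal),
             parastomal_hernia = stats::rbinom(n, 1, p_parastomal))
}

#' Generate synthetic study-level summaries for pooling
#'
#' Draws `k` study estimates from the standard random-effects data model:
#' study-specific true values `theta_i ~ Normal(true_mean, tau2)` observed
#' with within-study noise `Normal(0, within_var)`. The within-study
#' variance is recorded as known, so [pool_random_effects()] should recover
#' `true_mean` (within sampling error) and, at large `k`, `tau2`.
#'
#' @param k number of studies (>= 2).
#' @param true_mean grand mean of the study-level quantity.
#' @param tau2 between-study variance (>= 0).
#' @param within_var common within-study variance (> 0).
#' @param n nominal per-study sample size recorded in the output.
#' @param seed optional integer seed.
#' @return A [study_records()] data frame with `k` rows.
#' @examples
#' recs <- generate_study_summaries(20, true_mean = 26.41, tau2 = 0.5, seed = 1)
#' pool_random_effects(recs)
#' @export
generate_study_summaries <- function(k, true_mean = 26.41, tau2 = 0.5,
                                     within_var = 1, n = 100, seed = NULL) {
  stopifnot(k >= 2, tau2 >= 0, within_var > 0)
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::rnorm(k, true_mean, sqrt(tau2))
  est <- stats::rnorm(k, theta, sqrt(within_var))
  study_records(sprintf("study_%02d", seq_len(k)), est,
                variance = rep(within_var, k), n = rep(n, k))
}
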