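#' Configuration of the individual-patient Monte Carlo
#'
#' @param n_patients number of simulated patients (published run: 100,000).
#' @param seed integer seed; identical configurations reproduce bit-identical
#'   results.
#' @param probs a [probability_set()].
#' @param costs a [cost_set()].
#' @param high_risk_fraction probability (or, in deterministic mode, exact
#'   share) of high-risk patients; default 0.5 as in the published run.
#' @param class_draw `"bernoulli"` draws each patient's risk class
#'   independently; `"deterministic"` fixes exactly
#'   `round(n * high_risk_fraction)` high-risk patients.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 100000, seed = 1,
                       probs = probability_set(), costs = cost_set(),
                       high_risk_fraction = probs$high_risk_fraction,
                       class_draw = c("bernoulli", "deterministic")) {
  stopifnot(n_patients >= 1)
  if (high_risk_fraction < 0 || high_risk_fraction > 1)
    stop("'high_risk_fraction' must lie in [0, 1]")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 probs = probs, costs = costs,
                 high_risk_fraction = high_risk_fraction,
                 class_draw = match.arg(class_draw)),
            class = "sim_config")
}

draw_classes <- function(config) {
  n <- config$n_patients
  f <- config$high_risk_fraction
  if (config$class_draw == "deterministic") {
    n_high <- round(n * f)
    rep(c("high", "low"), c(n_high, n - n_high))
  } else {
    ifelse(stats::runif(n) < f, "high", "low")
  }
}

# Simulate one strategy given pre-drawn risk classes and hernia uniforms
# (enables common random numbers across strategies).
simulate_one <- function(strategy, config, classes, u_hernia) {
  probs <- config$probs; costs <- config$costs
  high <- classes == "high"
  mesh <- switch(strategy,
                 no_mesh = rep(FALSE, length(classes)),
                 mesh_all = rep(TRUE, length(classes)),
                 selective = high)
  p <- ifelse(mesh, probs$p_with_mesh,
              ifelse(high, arm_probability(strategy, "high", probs),
                     arm_probability(strategy, "low", probs)))
  hernia <- u_hernia < p
  cost <- ifelse(mesh, costs$closure_with_mesh, costs$closure) +
    costs$consults + hernia * costs$hernia_repair
  n <- length(classes)
  cea_result(strategy,
             mean_cost = mean(cost),
             effectiveness = mean(!hernia),
             mc_se_cost = stats::sd(cost) / sqrt(n),
             mc_se_eff = stats::sd(!hernia) / sqrt(n))
}

#' Individual-patient Monte Carlo for one strategy
#'
#' Per simulated patient: draw a risk class, apply the strategy's mesh rule,
#' draw the hernia outcome from the corresponding branch probability, and
#' accumulate cost and the hernia-free indicator. Returns the strategy's
#' mean cost and effectiveness with their Monte Carlo standard errors.
#'
#' @param config a [sim_config()].
#' @param strategy one of [strategies()].
#' @return One-row `cea_result` with nonzero `mc_se_*` columns.
#' @examples
#' simulate_strategy(sim_config(n_patients = 1000, seed = 7), "mesh_all")
#' @export
simulate_strategy <- function(config, strategy) {
  strategy <- match.arg(strategy, strategies())
  set.seed(config$seed)
  classes <- draw_classes(config)
  u <- stats::runif(config$n_patients)
  simulate_one(strategy, config, classes, u)
}

#' Individual-patient Monte Carlo for several strategies at once
#'
#' All strategies share one set of simulated patients (the same risk-class
#' and hernia-uniform draws), i.e. common random numbers, so incremental
#' comparisons are less noisy than independent runs. Strategy order is fixed.
#'
#' @param config a [sim_config()].
#' @param which character vector of strategies; default all three.
#' @return `cea_result` data frame, one row per strategy.
#' @export
simulate_strategies <- function(config, which = strategies()) {
  which <- match.arg(which, strategies(), several.ok = TRUE)
  set.seed(config$seed)
  classes <- draw_classes(config)
  u <- stats::runif(config$n_patients)
  do.call(rbind, lapply(which, simulate_one, config = config,
                        classes = classes, u_hernia = u))
}
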