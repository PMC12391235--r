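#' Uncertainty specification for probabilistic sensitivity analysis
#'
#' The publication states that hernia probabilities and costs were varied,
#' without naming distributions. The conventional choices are used: Beta for
#' probabilities, parameterised by method of moments from the point estimate
#' and an effective sample size (`alpha = p * n_eff`, `beta = (1 - p) *
#' n_eff`), and Gamma for costs with mean equal to the base cost and a fixed
#' coefficient of variation. Effective sample sizes default to the two
#' meta-analyses' pooled sizes: 2455 (risk-factor model probabilities) and
#' 2008 (mesh-model probabilities). The cost CV of 0.2 is pure convention —
#' the publication prints no cost uncertainty at all. Uniform alternatives
#' are provided for both, and lognormal for costs.
#'
#' `n_eff = Inf` and `cost_cv = 0` are the degenerate limits: draws collapse
#' to the base values exactly.
#'
#' @param n_eff_risk effective sample size behind the low/high-risk no-mesh
#'   probabilities.
#' @param n_eff_mesh effective sample size behind the pooled no-mesh and
#'   with-mesh probabilities.
#' @param cost_cv coefficient of variation applied to every unit cost.
#' @param prob_dist `"beta"` or `"uniform"` (uniform spans the +/- 1.96 SE
#'   interval, truncated to (0, 1)).
#' @param cost_dist `"gamma"`, `"lognormal"` or `"uniform"` (uniform spans
#'   +/- 1.96 SD, truncated at 0); all share the base mean and CV.
#' @return List of class `psa_uncertainty`.
#' @export
psa_uncertainty <- function(n_eff_risk = 2455, n_eff_mesh = 2008,
                            cost_cv = 0.2,
                            prob_dist = c("beta", "uniform"),
                            cost_dist = c("gamma", "lognormal", "uniform")) {
  if (n_eff_risk <= 0 || n_eff_mesh <= 0)
    stop("effective sample sizes must be positive")
  if (cost_cv < 0) stop("'cost_cv' must be non-negative")
  structure(list(n_eff_risk = n_eff_risk, n_eff_mesh = n_eff_mesh,
                 cost_cv = cost_cv,
                 prob_dist = match.arg(prob_dist),
                 cost_dist = match.arg(cost_dist)),
            class = "psa_uncertainty")
}

draw_prob <- function(p, n_eff, dist) {
  if (!is.finite(n_eff)) return(p)
  if (dist == "beta")
    return(stats::rbeta(1, p * n_eff, (1 - p) * n_eff))
  se <- sqrt(p * (1 - p) / n_eff)
  min(max(stats::runif(1, p - 1.96 * se, p + 1.96 * se),
          .Machine$double.eps), 1 - .Machine$double.eps)
}

draw_cost <- function(m, cv, dist) {
  if (cv == 0 || m == 0) return(m)
  sd <- cv * m
  switch(dist,
         gamma = stats::rgamma(1, shape = 1 / cv^2, scale = m * cv^2),
         lognormal = {
           s2 <- log(1 + cv^2)
           stats::rlnorm(1, log(m) - s2 / 2, sqrt(s2))
         },
         uniform = max(stats::runif(1, m - 1.96 * sd, m + 1.96 * sd), 0))
}

#' Sample one PSA draw of branch probabilities and unit costs
#'
#' @param probs base [probability_set()].
#' @param costs base [cost_set()].
#' @param uncertainty a [psa_uncertainty()].
#' @return List with elements `probs` and `costs` mirroring the input
#'   structures, each slot replaced by one random draw.
#' @export
sample_inputs <- function(probs, costs, uncertainty = psa_uncertainty()) {
  u <- uncertainty
  ps <- probs
  ps$p_low_no_mesh <- draw_prob(probs$p_low_no_mesh, u$n_eff_risk, u$prob_dist)
  ps$p_high_no_mesh <- draw_prob(probs$p_high_no_mesh, u$n_eff_risk, u$prob_dist)
  ps$p_no_mesh_pooled <- draw_prob(probs$p_no_mesh_pooled, u$n_eff_mesh, u$prob_dist)
  ps$p_with_mesh <- draw_prob(probs$p_with_mesh, u$n_eff_mesh, u$prob_dist)
  cs <- costs
  for (nm in names(costs))
    cs[[nm]] <- draw_cost(costs[[nm]], u$cost_cv, u$cost_dist)
  list(probs = ps, costs = cs)
}

quadrant_of <- function(de, dc) {
  if (de == 0 || dc == 0) return("boundary")
  if (de > 0) { if (dc > 0) "NE" else "SE" } else { if (dc > 0) "NW" else "SW" }
}

#' Probabilistic sensitivity analysis
#'
#' Per iteration: sample branch probabilities and unit costs from their
#' uncertainty distributions, compute each strategy's analytic expected cost
#' and effectiveness (second-order uncertainty only — no nested
#' microsimulation), and record the incremental cost and effectiveness of
#' each configured comparison. A draw is counted cost-effective when `ΔE >
#' 0` and its net monetary benefit `wtp * ΔE - ΔC` is non-negative. Each
#' draw is also assigned a cost-effectiveness-plane quadrant (`NE`, `SE`,
#' `NW`, `SW`); draws exactly on an axis go to a `boundary` bucket, which has
#' measure zero under continuous sampling.
#'
#' @param n_iterations number of PSA draws (published run: 10,000).
#' @param seed integer seed.
#' @param probs,costs base-case inputs.
#' @param uncertainty a [psa_uncertainty()].
#' @param comparisons list of `c(strategy_a, strategy_b)` pairs; the default
#'   compares each mesh strategy with no mesh and mesh-for-everyone with
#'   selective.
#' @param wtp willingness-to-pay threshold (pesos per hernia prevented).
#' @param high_risk_fraction mixture weight of the high-risk class.
#' @return List of class `psa_result` with `draws` (one row per iteration
#'   per comparison: sampled `ΔC`, `ΔE`, `nmb`, `quadrant`), `inputs` (the
#'   sampled parameters per iteration), and `summary` (per comparison: mean
#'   `ΔC`/`ΔE`, proportion cost-effective, quadrant shares).
#' @examples
#' psa <- run_psa(n_iterations = 200, seed = 42)
#' psa$summary
#' @export
run_psa <- function(n_iterations = 10000, seed = 1,
                    probs = probability_set(), costs = cost_set(),
                    uncertainty = psa_uncertainty(),
                    comparisons = list(c("mesh_all", "no_mesh"),
                                       c("mesh_all", "selective"),
                                       c("selective", "no_mesh")),
                    wtp = 58000000,
                    high_risk_fraction = probs$high_risk_fraction) {
  if (length(comparisons) < 1) stop("at least one comparison is required")
  set.seed(seed)
  strat <- unique(unlist(comparisons))
  cmp_lab <- vapply(comparisons, function(p) paste(p[1], "vs", p[2]), "")
  n_cmp <- length(comparisons)
  dC <- dE <- matrix(NA_real_, n_iterations, n_cmp)
  inp <- matrix(NA_real_, n_iterations, 8,
                dimnames = list(NULL, c("p_low_no_mesh", "p_high_no_mesh",
                                        "p_no_mesh_pooled", "p_with_mesh",
                                        names(costs))))
  for (i in seq_len(n_iterations)) {
    d <- sample_inputs(probs, costs, uncertainty)
    ev <- lapply(stats::setNames(strat, strat), function(s)
      expected_values(s, d$probs, d$costs, high_risk_fraction))
    for (j in seq_len(n_cmp)) {
      a <- ev[[comparisons[[j]][1]]]; b <- ev[[comparisons[[j]][2]]]
      dC[i, j] <- a$mean_cost - b$mean_cost
      dE[i, j] <- a$effectiveness - b$effectiveness
    }
    inp[i, ] <- c(unlist(d$probs[1:4]), unlist(d$costs))
  }
  de_v <- as.vector(dE); dc_v <- as.vector(dC)
  draws <- data.frame(
    iteration = rep(seq_len(n_iterations), times = n_cmp),
    comparison = rep(cmp_lab, each = n_iterations),
    delta_cost = dc_v, delta_effectiveness = de_v,
    nmb = wtp * de_v - dc_v,
    quadrant = ifelse(de_v == 0 | dc_v == 0, "boundary",
                      ifelse(de_v > 0, ifelse(dc_v > 0, "NE", "SE"),
                             ifelse(dc_v > 0, "NW", "SW"))),
    stringsAsFactors = FALSE)
  draws$cost_effective <- draws$delta_effectiveness > 0 & draws$nmb >= 0
  summ <- do.call(rbind, lapply(split(draws, draws$comparison), function(g) {
    qs <- table(factor(g$quadrant, c("NE", "SE", "NW", "SW", "boundary")))
    data.frame(comparison = g$comparison[1],
               mean_delta_cost = mean(g$delta_cost),
               mean_delta_effectiveness = mean(g$delta_effectiveness),
               prop_cost_effective = mean(g$cost_effective),
               t(as.matrix(qs / nrow(g))),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  inputs <- data.frame(iteration = seq_len(n_iterations), inp)
  structure(list(draws = draws, inputs = inputs, summary = summ,
                 wtp = wtp, n_iterations = n_iterations, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations, WTP %s\n",
              x$n_iterations, format(x$wtp, big.mark = ",")))
  print(data.frame(comparison = x$summary$comparison,
                   mean_dC = round(x$summary$mean_delta_cost),
                   mean_dE = round(x$summary$mean_delta_effectiveness, 4),
                   prop_CE = round(x$summary$prop_cost_effective, 3)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Proportion of PSA draws that are cost-effective (`ΔE > 0` and
#' `wtp * ΔE - ΔC >= 0`) as a function of the willingness-to-pay threshold.
#' Monotone non-decreasing in the threshold.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid numeric vector of thresholds.
#' @return Data frame with columns `comparison`, `wtp`,
#'   `prop_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 1e8, length.out = 41)) {
  do.call(rbind, lapply(split(psa$draws, psa$draws$comparison), function(g) {
    data.frame(comparison = g$comparison[1], wtp = wtp_grid,
               prop_cost_effective = vapply(wtp_grid, function(l)
                 mean(g$delta_effectiveness > 0 &
                        l * g$delta_effectiveness - g$delta_cost >= 0),
                 numeric(1)),
               stringsAsFactors = FALSE)
  }))
}

#' Cost-effectiveness plane of PSA draws
#'
#' Scatter of incremental effectiveness against incremental cost, one point
#' per draw and comparison, with the willingness-to-pay ray through the
#' origin.
#'
#' @param x a `psa_result`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.psa_result <- function(x, ...) {
  d <- x$draws
  comps <- unique(d$comparison)
  cols <- stats::setNames(seq_along(comps) + 1, comps)
  graphics::plot(d$delta_effectiveness, d$delta_cost,
                 col = cols[d$comparison], pch = 16, cex = 0.3,
                 xlab = "Incremental effectiveness (hernias prevented)",
                 ylab = "Incremental cost (COP)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  graphics::abline(a = 0, b = x$wtp, lty = 2)
  graphics::legend("topleft", legend = c(comps, sprintf(
    "WTP = %s", format(x$wtp, big.mark = ","))),
    col = c(cols, "black"), pch = c(rep(16, length(comps)), NA),
    lty = c(rep(NA, length(comps)), 2), bty = "n", cex = 0.8)
  invisible(x)
}
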