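#' Unit costs of the decision tree (2025 Colombian pesos)
#'
#' The published analysis costed each arm from a private hospital's tariffs:
#' stoma closure, stoma closure with simultaneous prosthetic mesh placement,
#' hernia repair with prosthetic mesh, and the anesthesiology plus general
#' surgery consultations. Those tariffs were not printed, so the defaults
#' here are round placeholders — they satisfy the structural constraints
#' (mesh closure costs more than plain closure) but are NOT the published
#' inputs, and absolute strategy costs computed from them are not comparable
#' with the publication's. Effectiveness and incremental-effectiveness
#' results do not depend on them.
#'
#' @param closure cost of stoma closure without mesh.
#' @param closure_with_mesh cost of closure with prophylactic mesh; must be
#'   at least `closure`.
#' @param hernia_repair cost of repairing an incisional hernia (incurred
#'   once per hernia).
#' @param consults anesthesiology + surgery consultation costs, attached
#'   once to every arm.
#' @return List of class `cost_set`.
#' @export
cost_set <- function(closure = 10000000,
                     closure_with_mesh = 10900000,
                     hernia_repair = 3000000,
                     consults = 250000) {
  v <- c(closure = closure, closure_with_mesh = closure_with_mesh,
         hernia_repair = hernia_repair, consults = consults)
  if (any(v < 0)) stop("all costs must be non-negative")
  if (closure_with_mesh < closure)
    stop("'closure_with_mesh' must be at least 'closure'")
  structure(as.list(v), class = "cost_set")
}

#' The three mesh-placement strategies
#'
#' @return Character vector `c("no_mesh", "selective", "mesh_all")`.
#' @export
strategies <- function() c("no_mesh", "selective", "mesh_all")

# Does this strategy give mesh to a patient of the given risk class?
mesh_given <- function(strategy, risk_class) {
  switch(strategy,
         no_mesh = FALSE,
         mesh_all = TRUE,
         selective = risk_class == "high",
         stop("unknown strategy: ", strategy))
}

# Hernia probability for one (strategy, risk class) arm.  Under the
# as_published variant the no-mesh strategy applies the pooled risk to all
# patients (reproducing the published 1 - 0.1939 = 0.8061); every other
# unmeshed arm uses its class-specific probability.
arm_probability <- function(strategy, risk_class, probs) {
  if (mesh_given(strategy, risk_class)) return(probs$p_with_mesh)
  if (strategy == "no_mesh" && probs$variant == "as_published")
    return(probs$p_no_mesh_pooled)
  if (risk_class == "high") probs$p_high_no_mesh else probs$p_low_no_mesh
}

#' Analytic expected cost and effectiveness of a strategy
#'
#' Closed-form expectation over the decision tree. Per arm, cost is the
#' index procedure plus consultations plus `P(hernia) * hernia_repair`;
#' effectiveness is the hernia-free probability `1 - P(hernia)`. Arms are
#' mixed by the high-risk fraction.
#'
#' @param strategy one of [strategies()].
#' @param probs a [probability_set()].
#' @param costs a [cost_set()].
#' @param high_risk_fraction mixture weight of the high-risk class;
#'   defaults to the one stored in `probs`.
#' @return One-row data frame of class `cea_result` with columns `strategy`,
#'   `mean_cost`, `effectiveness`, `mc_se_cost`, `mc_se_eff` (the latter two
#'   are 0 for analytic results).
#' @examples
#' expected_values("no_mesh", probability_set(), cost_set())
#' @export
expected_values <- function(strategy, probs, costs,
                            high_risk_fraction = probs$high_risk_fraction) {
  strategy <- match.arg(strategy, strategies())
  f <- high_risk_fraction
  if (f < 0 || f > 1) stop("'high_risk_fraction' must lie in [0, 1]")
  cost <- 0; eff <- 0
  for (cl in c("high", "low")) {
    w <- if (cl == "high") f else 1 - f
    if (w == 0) next
    p <- arm_probability(strategy, cl, probs)
    idx <- if (mesh_given(strategy, cl)) costs$closure_with_mesh else costs$closure
    cost <- cost + w * (idx + costs$consults + p * costs$hernia_repair)
    eff <- eff + w * (1 - p)
  }
  cea_result(strategy, cost, eff)
}

cea_result <- function(strategy, mean_cost, effectiveness,
                       mc_se_cost = 0, mc_se_eff = 0) {
  stopifnot(effectiveness >= 0, effectiveness <= 1,
            mc_se_cost >= 0, mc_se_eff >= 0)
  out <- data.frame(strategy = strategy, mean_cost = mean_cost,
                    effectiveness = effectiveness,
                    mc_se_cost = mc_se_cost, mc_se_eff = mc_se_eff,
                    stringsAsFactors = FALSE)
  class(out) <- c("cea_result", "data.frame")
  out
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes `ΔC = cost_a - cost_b`, `ΔE = eff_a - eff_b`, and when `ΔE != 0`
#' the ICER `ΔC / ΔE` in pesos per hernia prevented. Strategy `a` is
#' *dominant* when it is no more costly and strictly more effective (or
#' strictly cheaper and no less effective), *dominated* in the mirror case,
#' otherwise a *trade-off*. `a` is cost-effective when it is dominant or its
#' ICER is at most the willingness-to-pay threshold with `ΔE > 0`.
#'
#' @param a,b one-row `cea_result`s (from [expected_values()] or
#'   [simulate_strategy()]).
#' @param wtp willingness-to-pay threshold in pesos per hernia prevented;
#'   default 58,000,000 (two times Colombia's GDP per capita).
#' @return List of class `icer_record`: `comparison`, `delta_cost`,
#'   `delta_effectiveness`, `icer` (NA when `ΔE = 0`), `status`, `wtp`,
#'   `cost_effective`.
#' @examples
#' ps <- probability_set(); cs <- cost_set()
#' icer(expected_values("mesh_all", ps, cs), expected_values("no_mesh", ps, cs))
#' @export
icer <- function(a, b, wtp = 58000000) {
  dc <- a$mean_cost - b$mean_cost
  de <- a$effectiveness - b$effectiveness
  ic <- if (de != 0) dc / de else NA_real_
  status <-
    if (dc == 0 && de == 0) "equivalent"
    else if ((dc <= 0 && de > 0) || (dc < 0 && de >= 0)) "dominant"
    else if ((dc >= 0 && de < 0) || (dc > 0 && de <= 0)) "dominated"
    else "tradeoff"
  ce <- status == "dominant" || (de > 0 && !is.na(ic) && ic <= wtp)
  structure(list(comparison = paste(a$strategy, "vs", b$strategy),
                 delta_cost = dc, delta_effectiveness = de, icer = ic,
                 status = status, wtp = wtp, cost_effective = ce),
            class = "icer_record")
}

#' @export
print.icer_record <- function(x, ...) {
  cat(sprintf("%s: dCost = %s, dEff = %.4f", x$comparison,
              format(round(x$delta_cost), big.mark = ","),
              x$delta_effectiveness))
  if (!is.na(x$icer))
    cat(sprintf(", ICER = %s per hernia prevented",
                format(round(x$icer), big.mark = ",")))
  cat(sprintf(" [%s%s]\n", x$status,
              if (x$cost_effective) ", cost-effective" else ""))
  invisible(x)
}

#' Incremental analysis across all strategies
#'
#' Orders strategies by effectiveness, flags strongly dominated ones (some
#' other strategy is cheaper and at least as effective, or no costlier and
#' strictly more effective), computes sequential ICERs along the
#' non-dominated frontier (each strategy against the next-less-effective
#' non-dominated one, with extended dominance removed), and recommends the
#' most effective strategy whose sequential ICER does not exceed the
#' willingness-to-pay threshold.
#'
#' @param results a list of one-row `cea_result`s (two or more), or a
#'   `cea_result` data frame with one row per strategy.
#' @param wtp willingness-to-pay threshold (pesos per hernia prevented).
#' @return List of class `ce_frontier`: `table` (a data frame ordered by
#'   effectiveness with `dominated` flags and sequential ICERs) and
#'   `recommended`.
#' @export
frontier <- function(results, wtp = 58000000) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  if (nrow(results) < 2) stop("at least 2 strategies are required")
  tab <- results[order(results$effectiveness, results$mean_cost), ]
  n <- nrow(tab)
  # strong (simple) dominance by pairwise enumeration
  tab$dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n)[-i], function(j) {
      (tab$mean_cost[j] < tab$mean_cost[i] &&
         tab$effectiveness[j] >= tab$effectiveness[i]) ||
        (tab$mean_cost[j] <= tab$mean_cost[i] &&
           tab$effectiveness[j] > tab$effectiveness[i])
    }, logical(1)))
  }, logical(1))
  tab$seq_icer <- NA_real_
  # sequential ICERs with extended dominance on the non-dominated set
  repeat {
    idx <- which(!tab$dominated)
    if (length(idx) >= 2) {
      ic <- diff(tab$mean_cost[idx]) / diff(tab$effectiveness[idx])
      drop <- which(diff(ic) < 0)  # non-increasing ICER => extended dominance
      if (length(drop)) { tab$dominated[idx[drop[1] + 1]] <- TRUE; next }
      tab$seq_icer[idx[-1]] <- ic
    }
    break
  }
  idx <- which(!tab$dominated)
  ok <- idx[is.na(tab$seq_icer[idx]) | tab$seq_icer[idx] <= wtp]
  # frontier is ordered by effectiveness, so the last affordable step wins;
  # steps above an unaffordable one are unreachable
  rec <- tab$strategy[idx[1]]
  for (i in idx[-1]) {
    if (!is.na(tab$seq_icer[i]) && tab$seq_icer[i] <= wtp) rec <- tab$strategy[i]
    else break
  }
  rownames(tab) <- NULL
  structure(list(table = tab, recommended = rec, wtp = wtp),
            class = "ce_frontier")
}

#' @export
print.ce_frontier <- function(x, ...) {
  cat("Cost-effectiveness frontier (ordered by effectiveness)\n")
  print(data.frame(strategy = x$table$strategy,
                   mean_cost = round(x$table$mean_cost),
                   effectiveness = round(x$table$effectiveness, 4),
                   dominated = x$table$dominated,
                   seq_icer = round(x$table$seq_icer)))
  cat(sprintf("Recommended at WTP %s: %s\n",
              format(x$wtp, big.mark = ","), x$recommended))
  invisible(x)
}
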