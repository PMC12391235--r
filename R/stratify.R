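#' Assign high/low hernia-risk class to patients
#'
#' A patient is high risk when their predicted incisional-hernia probability
#' under the no-mesh risk model reaches the threshold; ties classify high
#' (conservative toward prevention). The default threshold 0.2280 is the
#' smallest single-factor high-risk probability under the published model (a
#' terminal colostomy at reference BMI), so a patient is high risk when BMI
#' is about 30 or more, or a parastomal hernia is present, or the stoma is a
#' terminal colostomy.
#'
#' @param patients data frame with columns `bmi`, `colostomy`, `terminal`,
#'   `parastomal_hernia` (flags coded 0/1; BMI in kg/m^2 within `[10, 80]`).
#' @param model a calibrated [calibrate_risk_model()] `risk_model`.
#' @param threshold probability in (0, 1); default 0.2280.
#' @param digits predicted probabilities are rounded to this many decimals
#'   before comparison (default 4, the precision at which the published
#'   probabilities — and hence the threshold — are stated; the
#'   terminal-colostomy profile predicts 0.22797, which ties with 0.2280
#'   only at this precision). `NA` compares unrounded.
#' @return Factor with levels `c("low", "high")`, one per patient.
#' @examples
#' m <- calibrate_risk_model(stoma_risk_summary())
#' classify_risk(data.frame(bmi = c(26.41, 30), colostomy = 0,
#'                          terminal = 0, parastomal_hernia = 0), m)
#' @export
classify_risk <- function(patients, model, threshold = 0.2280, digits = 4) {
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie strictly inside (0, 1)")
  if ("bmi" %in% names(patients) &&
      any(patients$bmi < 10 | patients$bmi > 80))
    stop("BMI outside the plausibility window [10, 80]")
  p <- predict(model, patients)
  if (!is.na(digits)) p <- round(p, digits)
  factor(ifelse(p >= threshold, "high", "low"), levels = c("low", "high"))
}

#' Branch probabilities of the mesh decision tree
#'
#' Assembles the four hernia probabilities driving the decision tree:
#' low-risk without mesh, high-risk without mesh, the pooled no-mesh risk,
#' and the risk with prophylactic mesh (the pooled risk odds-scaled by the
#' mesh odds ratio). One common with-mesh probability applies to every mesh
#' recipient regardless of risk class.
#'
#' Two variants resolve an ambiguity in how the published analysis combined
#' its two risk models:
#' \describe{
#'   \item{`as_published`}{uses the published 4-decimal branch probabilities
#'     (0.0906, 0.2280, 0.1939, 0.0481). Under this variant the no-mesh
#'     strategy applies the pooled risk 0.1939 to *all* unmeshed patients,
#'     which reproduces the published no-mesh effectiveness `1 - 0.1939 =
#'     0.8061` exactly — even though it is not consistent with a 50/50
#'     high/low mixture at 0.2280 / 0.0906.}
#'   \item{`internally_consistent`}{recomputes the high-risk probability so
#'     the mixture of risk classes equals the pooled no-mesh risk:
#'     `p_high = (p_pooled - (1 - f) p_low) / f`.}
#' }
#'
#' @param variant `"as_published"` or `"internally_consistent"`.
#' @param risk_model,mesh_model calibrated `risk_model` objects; defaults
#'   are fitted from [stoma_risk_summary()] / [mesh_effect_summary()].
#' @param p_pooled_no_mesh pooled hernia risk without mesh. Default 0.1939,
#'   the published figure; the full-precision mesh-model prediction is
#'   0.19367 (within 5e-4 — the published value carries intermediate
#'   rounding).
#' @param mesh_odds_ratio protective mesh effect on the odds scale (0.21).
#' @param high_risk_fraction mixture weight of the high-risk class (0.5).
#' @param digits rounding applied to model-derived probabilities for the
#'   `as_published` variant (4, matching the publication); `NA` for none.
#' @return List of class `probability_set` with elements `p_low_no_mesh`,
#'   `p_high_no_mesh`, `p_no_mesh_pooled`, `p_with_mesh`, `variant`,
#'   `high_risk_fraction`.
#' @examples
#' probability_set()
#' probability_set("internally_consistent")
#' @export
probability_set <- function(variant = c("as_published", "internally_consistent"),
                            risk_model = NULL, mesh_model = NULL,
                            p_pooled_no_mesh = 0.1939,
                            mesh_odds_ratio = 0.21,
                            high_risk_fraction = 0.5,
                            digits = 4) {
  variant <- match.arg(variant)
  if (is.null(risk_model)) risk_model <- calibrate_risk_model(stoma_risk_summary())
  rnd <- function(x) if (is.na(digits)) x else round(x, digits)
  ref <- as.data.frame(as.list(risk_model$reference_values))
  low <- ref; low[risk_model$kind == "binary"] <- 0
  p_low <- rnd(predict(risk_model, low))
  if (variant == "as_published") {
    # smallest single-factor high-risk profile: terminal colostomy at ref BMI
    hi <- low
    hi$colostomy <- 1
    hi$terminal <- 1
    p_high <- rnd(predict(risk_model, hi))
  } else {
    f <- high_risk_fraction
    if (f <= 0) stop("'high_risk_fraction' must be positive for this variant")
    p_high <- (p_pooled_no_mesh - (1 - f) * p_low) / f
  }
  p_mesh <- rnd(scale_odds(p_pooled_no_mesh, mesh_odds_ratio))
  new_probability_set(p_low, p_high, p_pooled_no_mesh, p_mesh,
                      variant, high_risk_fraction)
}

new_probability_set <- function(p_low, p_high, p_pooled, p_mesh,
                                variant, high_risk_fraction) {
  ps <- list(p_low_no_mesh = p_low, p_high_no_mesh = p_high,
             p_no_mesh_pooled = p_pooled, p_with_mesh = p_mesh,
             variant = variant, high_risk_fraction = high_risk_fraction)
  probs <- unlist(ps[1:4])
  if (any(probs <= 0 | probs >= 1))
    stop("all branch probabilities must lie strictly inside (0, 1)")
  if (p_mesh >= p_pooled)
    stop("mesh must be protective: p_with_mesh < p_no_mesh_pooled")
  if (high_risk_fraction < 0 || high_risk_fraction > 1)
    stop("'high_risk_fraction' must lie in [0, 1]")
  structure(ps, class = "probability_set")
}

#' @export
print.probability_set <- function(x, ...) {
  cat(sprintf("Decision-tree hernia probabilities (variant: %s)\n", x$variant))
  cat(sprintf("  low risk, no mesh   : %.4f\n", x$p_low_no_mesh))
  cat(sprintf("  high risk, no mesh  : %.4f\n", x$p_high_no_mesh))
  cat(sprintf("  pooled, no mesh     : %.4f\n", x$p_no_mesh_pooled))
  cat(sprintf("  with mesh           : %.4f\n", x$p_with_mesh))
  cat(sprintf("  high-risk fraction  : %.2f\n", x$high_risk_fraction))
  invisible(x)
}
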