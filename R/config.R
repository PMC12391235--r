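default_config <- function() {
  list(
    risk_summary = list(
      incidence = 0.1676,
      factors = list(
        list(name = "bmi", kind = "continuous", odds_ratio = 1.95, value = 26.41),
        list(name = "colostomy", kind = "binary", odds_ratio = 2.03, value = 0.53),
        list(name = "terminal", kind = "binary", odds_ratio = 1.46, value = 0.51),
        list(name = "parastomal_hernia", kind = "binary", odds_ratio = 3.42, value = 0.11)),
      n_patients = 2455),
    mesh_summary = list(incidence = 0.1238, odds_ratio = 0.21,
                        proportion = 0.34, n_patients = 2008),
    p_pooled_no_mesh = 0.1939,
    variant = "as_published",
    high_risk_fraction = 0.5,
    risk_threshold = 0.2280,
    wtp = 58000000,
    n_patients = 100000,
    n_psa = 10000,
    seed = 1,
    costs = list(closure = 10000000, closure_with_mesh = 10900000,
                 hernia_repair = 3000000, consults = 250000),
    uncertainty = list(n_eff_risk = 2455, n_eff_mesh = 2008, cost_cv = 0.2,
                       prob_dist = "beta", cost_dist = "gamma")
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])) && nm != "factors") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

check_that <- function(ok, key, constraint) {
  if (!ok) stop("config key '", key, "' violates constraint: ", constraint,
                call. = FALSE)
}

#' Load and validate an analysis configuration
#'
#' Reads a YAML or JSON configuration, fills unspecified keys from the
#' built-in base case, and validates every numeric constraint (incidences
#' and probabilities strictly inside their ranges, odds ratios positive,
#' costs non-negative with mesh closure at least as costly as plain
#' closure). Violations raise an error naming the offending key.
#'
#' The returned object carries a `provenance` attribute separating the
#' published inputs (incidences, odds ratios, covariate summary, WTP,
#' simulation sizes) from placeholder conventions (unit costs, cost CV,
#' BMI SD) that are not printed in the source publication.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults-only base case. An empty file also yields the base case.
#' @return A validated configuration list of class `run_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "paper_basecase.yaml",
#'                                package = "stomaCEA"))
#' cfg$wtp
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path)
    if (!is.null(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
      cfg <- merge_config(cfg, user)
    }
  }
  with(cfg, {
    check_that(risk_summary$incidence > 0 && risk_summary$incidence < 1,
               "risk_summary$incidence", "must lie strictly inside (0, 1)")
    check_that(mesh_summary$incidence > 0 && mesh_summary$incidence < 1,
               "mesh_summary$incidence", "must lie strictly inside (0, 1)")
    for (f in risk_summary$factors)
      check_that(f$odds_ratio > 0, paste0("risk_summary$factors[", f$name, "]"),
                 "odds_ratio must be > 0")
    check_that(mesh_summary$odds_ratio > 0, "mesh_summary$odds_ratio",
               "must be > 0")
    check_that(mesh_summary$proportion >= 0 && mesh_summary$proportion <= 1,
               "mesh_summary$proportion", "must lie in [0, 1]")
    check_that(p_pooled_no_mesh > 0 && p_pooled_no_mesh < 1,
               "p_pooled_no_mesh", "must lie strictly inside (0, 1)")
    check_that(variant %in% c("as_published", "internally_consistent"),
               "variant", "must be as_published or internally_consistent")
    check_that(high_risk_fraction >= 0 && high_risk_fraction <= 1,
               "high_risk_fraction", "must lie in [0, 1]")
    check_that(risk_threshold > 0 && risk_threshold < 1,
               "risk_threshold", "must lie strictly inside (0, 1)")
    check_that(wtp >= 0, "wtp", "must be non-negative")
    check_that(n_patients >= 1, "n_patients", "must be a positive integer")
    check_that(n_psa >= 0, "n_psa", "must be non-negative")
    check_that(all(unlist(costs) >= 0), "costs", "must be non-negative")
    check_that(costs$closure_with_mesh >= costs$closure,
               "costs$closure_with_mesh", "must be at least costs$closure")
    check_that(uncertainty$cost_cv >= 0, "uncertainty$cost_cv",
               "must be non-negative")
    check_that(uncertainty$n_eff_risk > 0 && uncertainty$n_eff_mesh > 0,
               "uncertainty$n_eff_risk/n_eff_mesh", "must be positive")
  })
  attr(cfg, "provenance") <- list(
    published = c("risk_summary", "mesh_summary", "p_pooled_no_mesh",
                  "high_risk_fraction", "risk_threshold", "wtp",
                  "n_patients", "n_psa"),
    placeholder = c("costs", "uncertainty$cost_cv", "seed"))
  class(cfg) <- c("run_config", "list")
  cfg
}

config_summaries <- function(cfg) {
  rs <- cfg$risk_summary
  fac <- do.call(rbind, lapply(rs$factors, function(f)
    data.frame(name = f$name, kind = f$kind, odds_ratio = f$odds_ratio,
               value = f$value, stringsAsFactors = FALSE)))
  ms <- cfg$mesh_summary
  list(risk = meta_summary(rs$incidence, fac, rs$n_patients),
       mesh = meta_summary(ms$incidence,
                           data.frame(name = "mesh", kind = "binary",
                                      odds_ratio = ms$odds_ratio,
                                      value = ms$proportion,
                                      stringsAsFactors = FALSE),
                           ms$n_patients))
}

# CSVs written with full double precision so files round-trip exactly
write_csv_full <- function(df, path) {
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis and write its report files
#'
#' Executes the pipeline end to end — calibrate both risk models, build the
#' branch probabilities, run the individual-patient microsimulation for the
#' three strategies, compute the pairwise incremental table and the
#' frontier, and (when `n_psa > 0`) run the probabilistic sensitivity
#' analysis — and writes `strategies.csv`, `icer_table.csv`,
#' `psa_draws.csv`, `summary.json` and `ce_plane.pdf` to `out_dir`. All
#' CSVs carry full double precision and no locale formatting, so reading
#' them back reproduces the in-memory results exactly.
#'
#' @param config a [load_config()] object (or `NULL` for the base case).
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the in-memory results and file paths.
#' @export
report <- function(config = NULL, out_dir = ".") {
  if (is.null(config)) config <- load_config()
  if (!inherits(config, "run_config")) stop("'config' must come from load_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

  sm <- stage("calibrate", config_summaries(config))
  risk_model <- stage("calibrate", calibrate_risk_model(sm$risk))
  mesh_model <- stage("calibrate", calibrate_risk_model(sm$mesh))
  probs <- stage("stratify", probability_set(
    config$variant, risk_model, mesh_model,
    p_pooled_no_mesh = config$p_pooled_no_mesh,
    mesh_odds_ratio = config$mesh_summary$odds_ratio,
    high_risk_fraction = config$high_risk_fraction))
  costs <- stage("costs", do.call(cost_set, config$costs))

  sim <- stage("microsim", simulate_strategies(sim_config(
    n_patients = config$n_patients, seed = config$seed,
    probs = probs, costs = costs,
    high_risk_fraction = config$high_risk_fraction)))

  pairs <- list(c("mesh_all", "selective"), c("mesh_all", "no_mesh"),
                c("selective", "no_mesh"))
  icers <- stage("icer", lapply(pairs, function(p)
    icer(sim[sim$strategy == p[1], ], sim[sim$strategy == p[2], ],
         wtp = config$wtp)))
  icer_tab <- do.call(rbind, lapply(icers, function(r)
    data.frame(comparison = r$comparison, delta_cost = r$delta_cost,
               delta_effectiveness = r$delta_effectiveness, icer = r$icer,
               status = r$status, cost_effective = r$cost_effective,
               stringsAsFactors = FALSE)))
  front <- stage("icer", frontier(sim, wtp = config$wtp))

  psa <- NULL
  if (config$n_psa > 0)
    psa <- stage("psa", run_psa(
      n_iterations = config$n_psa, seed = config$seed + 1,
      probs = probs, costs = costs,
      uncertainty = do.call(psa_uncertainty, config$uncertainty),
      wtp = config$wtp, high_risk_fraction = config$high_risk_fraction))

  paths <- list(strategies = file.path(out_dir, "strategies.csv"),
                icer_table = file.path(out_dir, "icer_table.csv"),
                summary = file.path(out_dir, "summary.json"))
  write_csv_full(as.data.frame(sim), paths$strategies)
  write_csv_full(icer_tab, paths$icer_table)
  if (!is.null(psa)) {
    paths$psa_draws <- file.path(out_dir, "psa_draws.csv")
    write_csv_full(psa$draws, paths$psa_draws)
    paths$ce_plane <- file.path(out_dir, "ce_plane.pdf")
    grDevices::pdf(paths$ce_plane, width = 7, height = 5)
    plot(psa)
    grDevices::dev.off()
  }

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE, digits = NA)
  summary <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed, psa_seed = if (config$n_psa > 0) config$seed + 1 else NULL,
    variant = config$variant,
    provenance = attr(config, "provenance"),
    intercepts = list(risk = risk_model$intercept, mesh = mesh_model$intercept),
    probabilities = probs[1:4],
    recommended = front$recommended,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("stomaCEA")))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  unlink(cfg_file)
  invisible(list(risk_model = risk_model, mesh_model = mesh_model,
                 probs = probs, strategies = sim, icer_table = icer_tab,
                 icers = icers, frontier = front, psa = psa, paths = paths))
}
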