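# Shared fixtures: the published-model calibrations and small input builders.

published_risk_model <- function() calibrate_risk_model(stoma_risk_summary())
published_mesh_model <- function() calibrate_risk_model(mesh_effect_summary())

# one-row covariate frame for the risk-factor model
patient <- function(bmi = 26.41, colostomy = 0, terminal = 0,
                    parastomal_hernia = 0) {
  data.frame(bmi = bmi, colostomy = colostomy, terminal = terminal,
             parastomal_hernia = parastomal_hernia)
}

# a random but valid cost set (used in property-style tests)
random_cost_set <- function() {
  closure <- runif(1, 5e6, 2e7)
  cost_set(closure = closure,
           closure_with_mesh = closure + runif(1, 0, 2e6),
           hernia_repair = runif(1, 1e6, 8e6),
           consults = runif(1, 0, 5e5))
}
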