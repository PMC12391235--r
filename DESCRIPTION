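Package: stomaCEA
Title: Cost-Effectiveness of Selective Prophylactic Mesh at Stoma Closure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic toolkit for evaluating prophylactic mesh
    placement strategies at stoma closure. Calibrates marginal logistic
    incisional-hernia risk models from meta-analytic summaries (incidence,
    odds ratios, covariate means) by intercept back-solving, stratifies
    patients into high and low hernia risk, evaluates a three-strategy
    decision tree (no mesh, selective mesh for high-risk patients, mesh for
    everyone) analytically and by individual-patient Monte Carlo
    microsimulation, computes incremental cost-effectiveness ratios against
    a willingness-to-pay threshold, and runs probabilistic sensitivity
    analysis on the cost-effectiveness plane. Includes a DerSimonian-Laird
    random-effects pooling utility and seeded synthetic cohort and
    study-summary generators.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tools,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
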