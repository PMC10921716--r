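Package: bioagesim
Title: Simulation-Based Evaluation of Cross-Sectional Biological Age Predictors
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study what cross-sectional biological-age "clocks" can
    and cannot recover. Provides synthetic-data generators for an additive
    latent biological-age model (a true/false marker pair, four three-marker
    coefficient scenarios, and a cohort emulator with Gompertz mortality and
    left-truncated follow-up), five age-predictor families (multiple linear
    regression, cross-validated ridge, Klemera-Doubal, first principal
    component, and naive equal/random weights), extraction of the
    age-independent divergence residual, and evaluation surfaces: recovery of
    the simulated divergence and Cox proportional-hazards association of the
    scaled divergence with mortality on the age timescale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
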