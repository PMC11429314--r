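Package: glyco
Title: Closed-Loop Glycemic Control Simulator with a PPO Insulin Controller
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An in-silico testbed for closed-loop insulin delivery in type 1
    diabetes. Implements the identifiable virtual patient (IVP) glucose-insulin
    ordinary differential equation model with meal glucose appearance, a
    continuous glucose monitor (CGM) layer with interstitial lag and
    second-order autoregressive sensor noise, a body-weight-scaled stochastic
    meal generator, four glycemic reward functions, a seeded reset/step
    reinforcement-learning environment with a 5-minute control interval, a
    proximal policy optimization (PPO) actor-critic controller with separate
    ELU block networks, and an evaluation pipeline computing time-in-range
    occupancy, RMSE-from-reference and control variability grid analysis
    (CVGA) summaries over a 13-scenario, 17-virtual-patient test protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    ggplot2,
    optparse
Config/testthat/edition: 3
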