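Package: gonogo
Title: Dual-Pathway Basal-Ganglia Learning of Action Payoffs and Costs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses a reinforcement-learning model of the
    basal ganglia in which the direct (Go) and indirect (No-Go) striatal
    pathways learn, from a single outcome prediction-error signal, the mean
    payoff and the mean cost of individual actions. Provides the piecewise
    linear prediction-error transform and weight-update rules with decay and
    zero-clipping, closed-form stochastic and deterministic equilibrium
    theory with parameter inversion and robustness analysis, reinforcement
    schedule generators, single-run and ensemble trajectory simulation, a
    dopamine-modulated choice model with an inaction default that reproduces
    D2-antagonist effects on willingness to work (including fitting to
    consumption data by derivative-free simplex optimisation), and
    actor-critic and opponent-actor-learning comparator rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
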