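Package: twourn
Title: Simulation and Modelling of the Two-Urn Belief-Updating Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulator and computational-modelling toolkit for a
    two-urn sampling task in which every payout is simultaneously a monetary
    outcome and probabilistic evidence about the urn's hidden long-term
    valence. Provides the task's event-distribution tables and deterministic
    trial schedules, an ideal (and prompt-anchored subjective) Bayesian
    belief learner with per-trial update and surprise measures, a
    Rescorla-Wagner delta-rule learner with payout range scaling, maximum
    likelihood estimation of the learning rate from reported beliefs via a
    log-distance objective, trial-wise belief-update regressions with edge
    nuisance coding, congruency contrasts and a per-trial Bayesianness score,
    plus a cohort of parameterised synthetic agents for end-to-end parameter
    recovery without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
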