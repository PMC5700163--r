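# twourn

Simulation and computational modelling of the **two-urn belief-updating
task** — a binary sampling task in which every drawn payout is two things at
once: a monetary outcome (short-term valence) and probabilistic evidence
about whether the chosen urn's long-term expected value is positive ("good")
or negative ("bad"). Because congruence between the two signals is
manipulated, the task dissociates model-free reward learning from
inference-based belief formation, and is a tool for studying how immediate
rewards bias beliefs that should, normatively, ignore them.

The package is aimed at computational cognitive scientists who want to
simulate the task, analyse behavioural session logs (their own or
synthetic), and validate the full analysis chain by parameter recovery.

## The task and models

Each 20-trial block draws events from a seven-row distribution. Informative
events have a fixed likelihood ratio between good and bad urns
(`p(E|good)/p(E|bad)` = 2.5 or 0.4); non-informative events (30% of mass,
including 10% zero payouts) have ratio 1. Payout magnitudes vary over four
block variants, but the expected value is always **±1.5 points per trial
(±30 per block)**. Sessions are 12 blocks = 240 trials; beliefs are prompted
on a 0–100 scale in steps of 10; correct end-of-block valence gambles earn
±5 bonus points; 10 points = 30 euro cents.

Three model components are implemented:

* **Bayesian learner** — iterative posterior
  `B' = p(E|good)·B / (p(E|good)·B + p(E|bad)·(1−B))`, per urn, reset to 0.5
  each block; yields the signed update ΔB, its magnitude D_KL = |ΔB|, and
  Shannon surprise. A *subjective* mode re-anchors each step to the
  participant's last prompted belief.
* **Rescorla–Wagner learner** — `δ_t = p_t − EV_t`,
  `EV_{t+1} = EV_t + α·δ_t` on payouts scaled to the block maximum; the
  learning rate is fit by maximising the log-distance objective
  `LD = Σ log(1 − |B_subj − B_EV|)` (grid + bounded refinement).
* **Belief-update regression** — per-participant OLS of normalized prompted
  updates ΔIBU on ΔB, RPE (or raw outcome) and a signed edge nuisance
  regressor, with group-level t tests, a congruency contrast and the
  per-trial `Bayesianness = 1 − |ΔB − ΔIBU|` score.

Synthetic agents close the loop: their generative update is the linear
hybrid `w_bayes·ΔB + w_rpe·δ + noise`, with edge attenuation, softmax
choices and an exploration bonus, so every analysis stage can be validated
against known ground truth.

## Worked example

```r
library(twourn)

cfg   <- task_config(rng_seed = 7)                  # 12 x 20 trials, original protocol
agent <- agent_params(w_rpe = 0.3, seed = 42)       # reward-biased updater
s     <- simulate_agent_session(cfg, agent)
s
#> <urn_session> 12 blocks x 20 trials (original mode, prompt every 1)
#>   total points: 790 (23.70 EUR)
#>   prompted trials: 240

fit_learning_rate(s)
#> <urn_alpha_fit> alpha = 0.4440, LD = -63.858 over 240 prompted trials

bt  <- run_bayesian_trace(s, "subjective")
rt  <- run_rl_trace(s, alpha = 0.06)
tab <- build_update_table(s, bt, rt)
fit_participant(tab, predictors = c("delta_b", "rpe", "edge"))
#> <urn_reg_fit> n = 240  -LL = -109.8
#> (Intercept)     delta_b         rpe        edge
#>     -0.0266      0.3558      0.4445      0.0000
#>   dropped constant predictors: edge
```

The regression recovers the agent's makeup: a positive weight on the
Bayesian update (it *is* mostly an inference machine) and a clearly
positive RPE weight (the planted reward bias). This particular agent's
marker never sat at 0 or 100 while updating, so the edge nuisance regressor
is constant and dropped with a flag. On a cohort,
`group_test(fits, "rpe")` and `congruency_contrast(tables)` give the
group-level statistics, and `recovery_experiment()` tabulates
true-versus-recovered parameters over a grid of agents.

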