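---
title: "Modelling belief updating in the two-urn task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling belief updating in the two-urn task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twourn)
```

## The task as a generative model

In the two-urn task a participant repeatedly chooses one of two lotteries
("urns") and draws a payout. Each payout is simultaneously money and
evidence: the seven possible events of a block occur with different
probabilities depending on whether the chosen urn is good (long-term
expected value +1.5 points per trial) or bad (−1.5). Informative events
have a likelihood ratio `p(E|good)/p(E|bad)` of 2.5 or 0.4; non-informative
events (30% of probability mass, of which 10% pay zero) are equally likely
under both valences and therefore carry reward but no evidence. An event is
*congruent* when its payout sign matches the valence it is evidence for,
*incongruent* when the two oppose — the lever that decouples reward
experience from normative inference.

`urn_events(variant)` encodes the seven-event table for each of the four
payout variants; probabilities never change across variants, only payout
magnitudes do, keeping expected values at exactly ±1.5 per trial:

```{r}
urn_events(1)
```

### Scheduling

The information content of a session is deterministic by design: each
20-trial block realizes an exact multiset of event classes (5
likely-congruent, 5 likely-incongruent, 2 unlikely-congruent, 2
unlikely-incongruent, 2 of each non-informative valence), shuffled under a
seed. Classes are defined *relative to the chosen urn*: a likely-congruent
draw from a good urn is the +50-style event, from a bad urn the −50-style
event. This is a design decision — the class taxonomy is the unique one
whose per-truth frequencies reproduce the event probabilities exactly while
letting the payout depend on the choice. Payout variants rotate round-robin
over blocks from a seeded offset. Ten blocks pair one good with one bad
urn; block 3 always has two bad urns (so that early beliefs about one urn
do not generalise to the other) and one seeded block at position ≥ 4 has
two good urns.

Trial indices are 1-based within block throughout (in memory and in the
CSV logs): a single indexing convention is less error-prone than mixing
0-based logs with 1-based reports.

## The Bayesian learner

Beliefs that the chosen urn is good update by Bayes' rule,

$$B_{t+1} = \frac{p(E_t \mid good)\,B_t}
  {p(E_t \mid good)\,B_t + p(E_t \mid bad)\,(1 - B_t)},$$

per urn, with the instructed prior of 0.5 restored at each block start and
the unchosen urn untouched. Note the denominator: it is the full predictive
probability of the event (second term weighted by `p(E|bad)`); any other
form would break normalization — and indeed the martingale property
`E[posterior] = prior`, which the test suite checks by brute-force
enumeration over the event support at tolerance 1e-12. Equal-likelihood
events return the prior bit-exactly, so "no update on non-informative
events" holds without floating-point noise.

Derived per-trial quantities: the **signed update** ΔB (posterior −
prior; the sign carries the direction of the evidence), its magnitude
**D_KL** = |ΔB| (the belief-change measure used as a regressor), and
**surprise** `I = −ln(B·p(E|good) + (1−B)·p(E|bad))` in nats (the log
base is a convention; natural log is used throughout). In this design
surprise and belief change are decoupled: rare non-informative events are
surprising yet never move beliefs.

The **subjective** mode applies the same one-step rule but re-anchors each
trial's prior to the participant's most recent prompted belief for the
chosen urn within the block (0.5, flagged, before the first prompt). This
is the variant that tracks what the participant should have concluded from
where they actually were, and is the default predictor source for the
regressions. Marker persistence versus reset (replication protocol) changes
what the participant sees, not the anchoring rule: in both modes the prior
is the last prompt for that urn in the block.

## The Rescorla–Wagner learner and the learning-rate fit

Model-free values track range-scaled payouts (`payout / max |payout| of the
block's variant`, an adjustment for range adaptation): `δ_t = p_t − EV_t`,
`EV_{t+1} = EV_t + α δ_t`. One EV is kept per urn and EVs reset to 0 at
block boundaries because the payout variant changes there; both are
documented choices (a single shared EV is available via `per_urn = FALSE`,
carry-over via `reset_blocks = FALSE`).

The learning rate is estimated by maximising the log-distance objective

$$LD = \sum_t \log(1 - |B_{subj,t} - B_{EV,t}|),$$

summed over prompted trials, where `B_EV = (EV+1)/2` maps the post-outcome
expected value of the chosen urn from [−1, 1] onto the belief scale. The
affine map is a declared commensuration decision: beliefs and EVs live on
different scales, and without a map the absolute difference can exceed 1,
making the log undefined. A raw-difference mode (`map_ev = FALSE`) is kept
for sensitivity analysis. Terms at |difference| = 1 are clipped at
1 − 1e-12. Each term is ≤ 0, so maximising LD means minimising the summed
log distance; concavity in α is *not* assumed — a 51-point grid brackets
the optimum before bounded scalar refinement, and the tests verify
agreement with an exhaustive 0.001-step grid to within 0.005. A flat
objective (e.g. constant beliefs with zero payouts) is reported as
`alpha = 0.5` with a `flat` flag rather than an arbitrary boundary value.

Nested regression models are compared by Gaussian negative log-likelihoods
and `likelihood_ratio_compare()`, a χ² test on twice the −LL difference.

## The belief-update regression

For each prompted trial the observed update is
`ΔIBU = (posterior prompt − prior prompt)/100`, the prior prompt being the
last confirmed marker for the chosen urn in the block (50 at block start).
Updates and predictors (ΔB, RPE, or the raw scaled outcome as a control)
are normalized per participant by the maximum absolute value — this is
deliberately distinct from standardized coefficients, which are available
via `normalize = "sd"`. The **edge** nuisance regressor is coded as the
predicted update direction gated on an extreme prior,
`sign(ΔB)·1{prior prompt ∈ {0, 100}}`, so a *negative* coefficient captures
attenuated updating at the scale's bounds; the coding and normalization
constant are configurable because neither is uniquely determined by the
measurement model. Constant predictor columns (an edge regressor of an
agent that never touches the bounds) are dropped with a flag — a constant
column carries no information and failing would be spurious; genuine
collinearity among varying predictors remains an error.

Group-level inference is a two-sided one-sample t test of the
per-participant coefficients (two-sided because the direction of the reward
bias is the question, not an assumption). The congruency contrast projects
raw updates onto the information direction (`ΔIBU · info_dir`) and
compares congruent against incongruent informative trials in a paired t
test: an ideal Bayesian shows no contrast (both classes carry the same
likelihood ratio), a reward-biased updater shows congruent > incongruent.
`Bayesianness = 1 − |ΔB − ΔIBU|` scores each trial's similarity to ideal
updating, returned unclipped.

## The synthetic agent

The generative agent mirrors the regression model — the linear hybrid

$$\Delta belief = w_{bayes}\,\Delta B + w_{rpe}\,\delta + \epsilon,
  \qquad \epsilon \sim N(0, noise\_sd^2),$$

attenuated by `edge_shrink` while the urn's marker sits at 0 or 100,
clipped to [0, 1]. Linearity is a choice that makes recovery well-posed;
multiplicative biases are out of scope. The internal belief stays
continuous; discretization to steps of 10 happens only at prompting
(`discretize = FALSE` yields continuous prompts, used by the identity-agent
tests, where prompts must equal the normative trace exactly). Choices are a
softmax over current beliefs plus an exploration bonus that decays with the
urn's within-block choice count; block-end gambles guess "good" above
0.5 + margin, "bad" below 0.5 − margin, and abstain between (margin 0.1).

Defaults define one fixed set of study conditions: `w_bayes = 1`,
`w_rpe = 0`, `alpha = 0.06`, `edge_shrink = 0.3`, `noise_sd = 0.05`,
`choice_temperature = 0.4`, `exploration_bonus = 0.3`. The two choice
parameters were calibrated once so that a default cohort reproduces the
reported human choice profile — roughly 150 of 240 draws from the good urn,
with the bad urn still sampled in essentially every block — and were then
frozen. Cohorts default to n = 24 agents under a shared event schedule
(the constant-information design); each agent gets a derived seed, and
sessions, cohorts and recovery experiments are bit-reproducible under a
fixed master seed.

### What the generator does and does not emulate

It emulates: per-urn belief trajectories driven by a Bayesian+RPE hybrid,
edge attenuation, response noise, 10-step discretized prompts,
exploitative-but-exploratory sampling, and abstention-capable gambles. It
does not emulate: reaction times, within-trial deliberation, memory decay
over blocks, or individual differences beyond the parameter vector. Two
consequences worth naming. First, passing recovery tests shows the analysis
chain is consistent, not that humans follow the linear hybrid. Second,
synthetic belief trajectories track the Bayesian posterior more faithfully
than human prompts do, so the fitted learning rate of a default cohort
(~0.3) is substantially higher than reported human estimates (~0.06):
the MLE α reflects how fast reported beliefs move, and simulated beliefs
move at near-ideal speed. The package therefore treats the human α as
sample-dependent and validates the fitter by parameter recovery on planted
α values instead (r ≥ 0.9, MAE ≤ 0.03 over 50 sessions in the test suite).

## Numerical choices and degenerate inputs

* Beliefs of exactly 0/1 are absorbing in the Bayes step; a predictive
  probability of zero raises an error (surprise returns `Inf`).
* Equal-likelihood events short-circuit to the prior, keeping the
  non-informative invariants exact.
* LD clipping at 1 − 1e-12; optimizer tolerance 1e-6 on α.
* Zero-variance coefficient vectors in group tests yield ±Inf t with a
  flag instead of an error (the all-identical-agents limit).
* Degenerate regressions (constant response) are flagged, not failed.
* Problem sizes in the shipped tests — cohorts of 8–24 agents, 50
  recovery sessions, a 10,000-trial frequency audit — were chosen as the
  smallest sizes at which the checked properties are statistically stable.

## Known limitations

* The class taxonomy, variant rotation and both-good block placement are
  principled reconstructions of an under-determined design; all are seeded
  and configurable.
* The EV→belief affine map is a modelling decision, not an identity; raw
  mode is provided precisely so its influence can be measured.
* Group tests assume approximately normal coefficient distributions across
  participants (as one-sample t tests do).
* The agent's gamble policy thresholds its final internal belief; humans
  presumably integrate more context between blocks.
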