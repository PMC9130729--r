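---
title: "Modelling learning-induced adult neurogenesis in the zebrafish pallium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling learning-induced adult neurogenesis in the zebrafish pallium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Adult zebrafish keep adding neurons to their pallium throughout life, and
spatial learning boosts that addition in circumscribed regions. `nscdyn`
implements a stochastic population-dynamics model of how a cohort of
thymidine-analog-labeled (BrdU/EdU) neural stem cells (NSCs) evolves into
adult-born neurons, and how learning reshapes that evolution through two
mechanisms: accelerated NSC proliferation during training and rescue of
immature neurons from a maturation death checkpoint.

Three labeled populations are tracked: reservoir NSCs `r` (self-renewing,
conserved), operative NSCs `o` (the neurogenic pool), and post-mitotic
neurons `n`. Six reactions connect them, with per-day rate constants taken
as fixed published values (Than-Trong et al. 2020); no rate is fitted here:

| # | reaction        | rate            | division? |
|---|-----------------|-----------------|-----------|
| 1 | r -> r + o      | k1 = 0.007      | yes       |
| 2 | o -> (death)    | k2 = 0.017      | no        |
| 3 | o -> o + o      | k3 = 0.006      | yes       |
| 4 | o -> o + n      | k4 = 0.018      | yes       |
| 5 | o -> n + n      | k5 = 0.004      | yes       |
| 6 | o -> n          | k6 = 0.013      | no        |

Reaction 1 does not consume the reservoir cell, and nothing kills
reservoir cells, so `dr/dt = 0` structurally: the labeled reservoir count
is an invariant of every simulation, not a simulated quantity.

## Equilibrium algebra and the operative-pool balance

Writing the mass balance of the operative pool — gains `k1*r + k3*o`
(reaction 3 adds one net cell), losses `(k2 + k5 + k6)*o` (reactions 2, 5
and 6 each remove the operative cell) — gives

    do/dt = k1*r - (k2 + k5 + k6 - k3)*o

so the pool is stable only when `beta = k2 + k5 + k6 - k3 > 0`, and its
stationary size is `o_eq = k1*r_eq / beta`. With the reference rates
`beta = 0.028` and `o_eq = r_eq / 4` exactly. `equilibrium_ratio()`
refuses a non-positive `beta` rather than returning a negative pool; the
mean-field oracle additionally handles the degenerate `beta = 0` case
(e.g. all rates zero) as linear growth.

At the stationary state each division reaction fires at a constant
population rate, so the fraction of divisions of each type is just the
normalised weight vector `(k1*r_eq, k3*o_eq, k4*o_eq, k5*o_eq)`:
exactly `(1/2, 3/28, 9/28, 1/14)`, i.e. `(0.50, 0.11, 0.32, 0.07)` to two
decimals. `estimate_division_proportions()` confirms this with a
stochastic census and is the package's empirical route to the same
numbers; the census and the analytic formula are checked against each
other in the test suite.

## Labeled cohorts

A thymidine-analog pulse labels cells in S-phase, so each of the `p0`
labeling divisions contributes exactly two labeled daughters, partitioned
by the division proportions:

    r0 = p0*d1,  o0 = p0*(d1 + 2*d3 + d4),  n0 = p0*(d4 + 2*d5)

`init_labeled_cohort()` rounds `r0` and `o0` and sets
`n0 = 2*p0 - r0 - o0`, so the two-daughters identity is conserved
bit-exactly for every input. The cohort size behind published figure axes
is not stated anywhere we could anchor it, so the package default is
`p0 = 1000` (all endpoints scale linearly with `p0` in expectation; the
per-`p0` fraction outputs are the scale-free quantities). With the
two-decimal proportions this gives `(r0, o0, n0) = (500, 1040, 460)`.

## The stochastic engine

`simulate_cohort()` is an exact event-driven simulation with
population-level propensities: reaction 1 fires at `k1'*r0` and each
operative cell fires reactions 2-6 at `k2, k3', ..., k6'`. Primes denote
the learning factor `lambda` (default 3) applied inside training windows;
`k2`, the death of operative NSCs, is deliberately never scaled — learning
accelerates division and differentiation, while neuronal loss has its own
rescue mechanism. The "doubled rates" scenario variant follows the same
reading and multiplies `k1, k3..k6` only.

Numerical design choices:

* **Piecewise-constant propensities.** Waiting times are exponential
  draws; at a training-window boundary the pending draw is discarded and
  redrawn under the new rates (valid by memorylessness).
* **Checkpoint stops do not touch the reaction clock.** Neuron deaths
  change no propensity, so the pending reaction time is kept across
  checkpoint days. Together with the next point this makes death-on and
  death-off runs of the same seed share an identical reaction event
  stream — paired survival estimates are coupled, which removes the
  between-run trajectory noise from the survival ratio.
* **A dedicated RNG substream for survival draws.** Checkpoint Bernoulli
  draws come from a second generator state derived from the seed, so
  enabling death (or setting `p_death = 0`) cannot perturb the reaction
  sequence.
* **Per-cell identity only where it pays.** Cells are interchangeable
  within a pool except for a lineage id (one per labeling division) and,
  for neurons, a birth time. That suffices for the two per-cell outputs:
  mean divisions per lineage and the age-based death checkpoint.
* **Determinism.** Same seed and configuration give bit-identical output;
  scenario seeds derive from the master seed plus a hash of the scenario
  name, so battery results do not depend on execution order.

## The death checkpoint and its semantics

Each labeled neuron matures for `checkpoint_age = 15` days and then faces
one Bernoulli draw: death with `p_death = 0.550`, divided by
`rescue_factor = 10` when the checkpoint day falls inside a training
window. The checkpoint rule is *age-based* and includes the `n0` cohort
(age 0 at labeling, checkpoint on day 15); neurons younger than 15 days
at the horizon never face the draw. An important consequence of the
age-based rule: for training at 12-30 days post-labeling, every neuron
born before day 15 — including the whole initial cohort — has its
checkpoint inside the window and is rescued, whereas for 3-14 training no
checkpoint day can fall inside the window at all. That asymmetry, not the
proliferation boost, is what makes the late training period pull far
ahead once death is enabled; without death the two periods end within
about 10% of each other.

Alternative bookkeepings (a single calendar-day-15 cull, exclusion of the
initial neurons, or reading 0.550 as a survival rather than death
probability) shift the control survival fraction at day 30 by roughly
5-20 percentage points while leaving every qualitative contrast
unchanged. The package implements the age-based death-probability rule
throughout; under it the expected control survival at 30 days is about
60%, which the paired-run tests reproduce.

## The mean-field oracle

`expected_trajectory()` solves the mean equations in closed form on each
constant-rate interval (`o` relaxes exponentially toward `k1'*r0/beta`
with rate `beta`; `n` integrates `(k4' + 2*k5' + k6')*o` exactly) and
chains the pieces across window boundaries. It is validated against an
independent general-purpose integrator (`deSolve::lsoda`, tolerances
1e-12) to 1e-8 relative in the test suite, and the stochastic ensembles
are in turn required to match it within three Monte-Carlo standard
errors. `expected_divisions()` gives the closed-form mean divisions per
lineage, `1 + (k1'*r0*T + (k3'+k4'+k5')*int o dt)/p0`, about 1.73 for the
30-day control; `expected_alive_neurons()` adds a deterministic death
approximation (survival factor applied to the checkpoint-faced birth
mass) used for validation bands only, since it carries no variance.

## Scenarios, seeds and problem sizes

`default_battery()` bundles the standard conditions: control and the two
training windows (contiguous calendar intervals `[3, 14)` and `[12, 30)`
by default; a 5-days-on/2-days-off session-block mode mirroring the
behavioural protocol is available via `session_blocks = TRUE`), each with
and without death, the doubled-`lambda` and doubled-rates variants with
death, and a 500-day control long run. Summaries store per-replicate
endpoints so every statistic is recomputable from the persisted JSON.

The package's standard problem sizes are `p0 = 1000` labeling divisions
and 20 replicates per condition (matching the published simulation N);
the qualitative battery contrasts and the oracle-convergence checks in
the test suite use 200 replicates, where Monte-Carlo standard errors on
endpoint means fall to a few cells. The 500-day long run demonstrates
that neuronal accumulation remains additive under death: the operative
pool relaxes to its equilibrium while surviving neurons keep
accumulating, roughly 2.4-fold between day 30 and day 500 in ensemble
mean.

## Synthetic per-fish counts

`generate_fish_counts()` emulates per-fish BrdU+NeuN+ counts from
published group summaries (mean, SE, N) with a zero-truncated normal:
location the printed mean, scale `se * sqrt(n)`, drawn by inverse CDF for
exact seed reproducibility. The truncated normal was preferred to a
lognormal for transparency: its two parameters are the printed summary
statistics themselves. The price is a truncation bias — at the published
control dispersion (mean 57.73, SD about 58) the realised mean sits about
29% above the location parameter, and the realised Trained/Control ratio
correspondingly below the ratio of printed means; the bias is computed
analytically (`sigma*phi/Phi`) and verified in the calibration tests.
The generator emulates per-fish totals only: no sectioning, imaging or
within-fish count structure, no between-batch effects. Passing its
calibration tests therefore says the model-vs-data comparison machinery
works, not that the model fits any real fish.

## Known limitations

* Only the labeled cohort is simulated; the unlabeled background, spatial
  structure, migration and differentiation-stage substates are out of
  scope.
* The oracle covers means only; fluctuation checks rely on replicate
  ensembles.
* The survival percentage is sensitive to checkpoint bookkeeping (above);
  comparisons across implementations should fix that convention first.
* Rates are constants from clonal-imaging work in the medial pallium;
  applying the model to other niches means re-deriving the equilibrium
  and census from new rates, which the analytic functions support.
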