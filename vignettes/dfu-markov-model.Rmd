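---
title: "A calibrated Markov model of diabetic foot ulcer care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A calibrated Markov model of diabetic foot ulcer care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfucea)
```

## The decision problem

Diabetic foot ulcers (DFUs) are chronic, recurrent, and expensive: an
unhealed ulcer can become infected, progress to gangrene, and end in
amputation. `dfucea` implements a decision-analytic evaluation of adding a
topical macrophage-regulating agent (ON101 cream) to general wound care
(GWC) versus GWC alone, from a health-care-sector perspective, for patients
presenting with an uninfected DFU.

The disease model is a six-state discrete-time Markov chain with a 1-month
cycle: `healed`, `uDFU` (uninfected ulcer), `iDFU` (infected ulcer),
`gangrene`, `postamputation`, and absorbing `death`. The whole cohort starts
in `uDFU` and is propagated for 60 cycles (5 years). Both arms share every
transition probability except the healing transition `uDFU -> healed`, which
the intervention improves by a relative effect size reported as an odds
ratio (OR 2.30, range 1.15–3.45).

Outcomes are discounted (3%/year, applied per cycle as $(1+r)^{-t/12}$)
total cost in 2021 USD, life-years, and quality-adjusted life-years (QALYs:
occupancy-months weighted by yearly state utilities divided by 12). Costs
decompose into a one-time initial-ulcer cost at cycle 0, monthly state
costs, one-time hospitalization costs charged on specific transitions
(infection, amputation, post-amputation complications), and the monthly drug
cost in the intervention arm. The headline statistic is the incremental
cost-effectiveness ratio ICER $= \Delta C / \Delta Q$, judged against
willingness-to-pay thresholds of \$32,787 and \$98,361 per QALY (1x and 3x
per-capita GDP of the study setting).

## Structural ambiguity and the calibration harness

Published model-input tables list exit probabilities per state; the residual
self-transition is implied. Three of the printed rows of this model,
however, do not admit a unique reading, and the literal reading is
internally inconsistent with the published outcome profile:

* **`iDFU to iDFU 0.084`** — a printed self-transition is redundant (the
  residual already implies it). Read literally, infected ulcers linger and
  iDFU occupancy at 5 years comes out at 7–15%, versus the published
  1.0–1.3%. The published profile requires the infected state to drain at
  roughly 0.9/month. We therefore also support the reading that 0.084 *is*
  the self-transition and the unlisted residual is the exit (to `healed`,
  i.e. resolution of the infected episode, or to `uDFU`).
* **`Healing to progression 0.038` / `Healing to iDFU 0.211`** — 0.211 as a
  literal monthly probability of a healed ulcer becoming an infected ulcer
  empties the healed state within months, which contradicts the published
  mean time healed (47–53 of 60 months). Supported readings: literal; a
  conditional split (recurrence 0.038, of which 21.1% infected); and a
  total-recurrence reading in which 0.038 is the marginal probability of an
  *uninfected* recurrence, every recurrence re-enters `uDFU`
  (total $0.038/(1-0.211) = 0.0482$/month) and later infection is carried by
  the modelled `uDFU -> iDFU` pathway.
* **`Postamputation to gangrene 0.43`** — literal reading creates a
  gangrene/post-amputation loop with repeated hospitalization charges and a
  cost level roughly 40% above the published totals. Supported readings:
  literal; conditional split of the 0.007 complication exit; and the product
  of the two printed values.

Neither the scale on which the OR is carried onto the monthly probability
nor the reward-timing convention is stated, so these are part of the same
configuration space: effect on the odds scale
($p' = \mathrm{OR}\,p/(1-p)\,/\,(1+\mathrm{OR}\,p/(1-p))$) or the rate scale
($p' = 1-(1-p)^{\mathrm{OR}}$, i.e. the effect multiplies the per-cycle
hazard — a common practice in applied state-transition models); rewards
accrued at end-of-cycle occupancy or with a trapezoid half-cycle correction;
drug cost accruing in `uDFU` only or in `uDFU` and `iDFU`.

`calibrate_structure()` makes the selection reproducible and falsifiable.
It enumerates the full candidate space (360 configurations) and ranks it in
two lexicographic stages:

1. **Occupancy profile.** A configuration passes if all eight published
   cumulative state probabilities at 5 years (healed/uDFU/iDFU/
   post-amputation, both arms) are reproduced within 2 percentage points and
   both published mean-months-healed within 2 months. Twenty configurations
   pass; the literal reading misses by more than 40 points.
2. **Results table.** Passing configurations are ordered by mean relative
   error against the published per-arm costs and QALYs and their increments.

The winner — total-recurrence healed row, printed-self iDFU row with
residual to `healed`, conditional-split post-amputation row, rate-scale
effect, half-cycle correction, drug cost in `uDFU` only, uncapped — is
recorded in the shipped model file `on101_dfu.yaml`; the literal variant
ships alongside (`on101_dfu_literal.yaml`) and both are regression-tested.
It reproduces the occupancy profile within 1.4 points and 0.7 months,
and lands the incremental QALYs (0.0379 vs published 0.0383), the
cost-saving break-even drug-cost multiplier (85% vs 85%), the two-way
threshold odds ratios (1.28/1.92 vs 1.30/1.98), and the acceptability
probabilities (see below) at the published values.

The exported `or_adjust_probability()` keeps the conventional odds
transform; the rate-scale reading is a property of the shipped model's
strategy configuration (`effect$scale`), not of the operator. The package
*defaults* (no half-cycle correction, odds scale) remain the
least-assumption conventions; the shipped file overrides them explicitly,
so everything a reader might contest is visible in the model definition.

```{r calibration, eval = FALSE}
# Re-run the harness (a few seconds); the winner matches the shipped file
cal <- calibrate_structure(load_paper_parameters("literal"))
head(cal)
attr(cal, "best")
```

## What the model does not reproduce

Two published quantities stay outside their tolerances under every
convention in the candidate space, and are reported as such rather than
patched:

* the **incremental cost** comes out at \$466 versus the published \$571
  (−18%). The end-of-cycle, trapezoid and start-of-cycle reward conventions
  bracket the published value (180 / 466 / 751) without hitting it; the
  residual gap tracks the infected-DFU aversion (below).
* the **1-year-horizon ICER** comes out at ≈\$13,800/QALY versus the
  published \$9,459/QALY. The published incremental-cost trajectory
  (≈\$115 at 12 cycles rising to \$571 at 60) is not attainable jointly
  with the 5-year profile under a single reward-timing convention.
* relatedly, the cohort-expected **infected-DFU events averted** are ≈2,460
  per 10,000 patients versus the published 2,766 (−11%), while healing
  events gained agree (cohort expectation ≈2,700 vs 2,787, with a
  Monte-Carlo standard error near 280 at 10,000 patients per arm under
  independent streams).

These are stated here once and visible in the acceptance tests; no
parameter was moved to close them.

## Uncertainty analyses

**PSA.** Each of 10,000 iterations draws every parameter independently from
its recorded family: beta for probabilities (method of moments, mean =
base, sd = range/3.92, ranges read as approximate 95% intervals), uniform
for utilities, triangular (low, mode = base, high) for costs, lognormal for
the OR (median = base, sdlog = log-range/3.92). Draws whose expanded rows
exceed unit exit probability are resampled and counted rather than
truncated, so marginals are not silently distorted. Matrices are rebuilt
and both arms re-run per draw. The summary reports the median ICER and the
net-monetary-benefit acceptability curve; the mean of signed per-iteration
ICERs is exported too, because that pathological average is sometimes
quoted, but it is flagged in the report metadata. At 10,000 iterations and
seed 1 the model gives acceptability 0.81 at \$98,361 and 0.60 at \$32,787
(published: 0.818 and 0.597) and a median ICER near \$16,000 (published
\$19,891, within its 25% band).

**Tornado / one-way DSA.** Every parameter moves to its stored bounds
(±50%; utilities ±10%) one at a time; entries with an ICER span above 40%
of base are flagged. The healing OR dominates, drug cost is second —
matching the published ranking.

**Two-way threshold and break-even.** Roots are found by bisection on the
sign of incremental net monetary benefit (equivalent to ICER = threshold
where the ICER is defined, and robust where it is not), to 0.005 on the OR
and 0.001 on the drug-cost multiplier, brackets [1, 3.45] and [0, 10].
Non-bracketing criteria return explicit "always"/"never"/unbracketed
results, never exceptions. Incremental cost is strictly increasing in the
drug-cost multiplier, so break-even roots are unique.

**Microsimulation.** Clinical events are counted on 10,000 simulated
patients per arm (categorical draws per cycle, vectorized; byte-identical
given the seed; arms use independent streams by default with a
common-random-numbers option). An event is *every* entry transition into
healed/iDFU/gangrene/post-amputation — counting once per patient cannot
yield thousands of extra healings among 10,000 patients in a recurrent
disease. Convergence to the cohort trace is tested at 3 binomial standard
errors.

## The random-model generator

`generate_random_model()` builds arbitrary valid parameterizations (random
row-stochastic structure with an absorbing death state, uniform utilities,
lognormal costs, log-uniform effect size on [0.5, 4], ±50/±10% ranges) for
property tests: row-stochasticity, the matrix-power oracle, QALY/life-year
identities, PSA machinery. It emulates structural variety, not clinical
realism — generated models have no recurrent-episode anatomy, no
event-cost topology, and no calibration targets, so generator-based tests
certify the *engine*, while everything specific to DFU economics is tested
on the shipped fixture.

## Numerical choices and problem sizes

* Row-sum tolerance 1e-12 on built matrices; cohort conservation checked at
  1e-10 against an independent matrix-power accumulation.
* Residual self-transitions are clamped at zero when listed exits sum to
  1 within 1e-9; sums beyond that are validation errors naming the row.
* Mean months per state are undiscounted end-of-cycle occupancy sums,
  independent of the reward-timing convention; cumulative probabilities are
  horizon-cycle occupancies.
* Life-years credit nothing within the cycle of death, consistent with the
  no-partial-credit reading of a monthly chain.
* Default analysis sizes mirror the study conditions: 60 cycles, 10,000
  PSA iterations, 10,000 microsimulated patients per arm; the full test
  suite and the acceptance script run in a few minutes on one core.

## Limitations

The model is time-homogeneous (no tunnel states, no age-specific background
mortality, no time-varying probabilities) and takes the published inputs as
given rather than re-deriving them from their original sources. Subgroup
effect sizes are not shipped — subgroup analyses publish no main-text ORs —
so subgroup runs accept a user-supplied OR via `run_scenario()`. The
cross-country cost adaptation (`adapt_costs()`) is a generic three-factor
transform; the original exchange-rate and price-index series are not
printed, so it is not fixture-anchored. All structural conclusions above
are conditional on the calibration targets being the published profile; a
user who disagrees can switch any interpretation tag in the YAML and rerun.
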