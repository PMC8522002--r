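---
title: "Markov cohort cost-effectiveness modelling with markovce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov cohort cost-effectiveness modelling with markovce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovce)
```

## The model and its assumptions

`markovce` implements a discrete-time Markov cohort model for two-arm
cost-effectiveness analysis. A cohort of identical units is distributed
over a small set of mutually exclusive states; each cycle the
distribution is multiplied by a fixed row-stochastic transition matrix.
The model is memoryless between cycles and time-homogeneous: the same
matrix applies at every cycle, so there are no tunnel states,
history-dependent transitions, or cycle-dependent dynamics. Those are
deliberate scope limits, not oversights — they keep the model
identifiable from the sparse inputs available in *ex-ante* evaluation,
where transition probabilities come from projections or analogous
projects rather than observed data.

Costs and effects attach to states, not transitions. Per cycle, a unit
in state *i* accrues a running cost (a state-independent periodic
service cost plus a state-specific indirect cost) and an effect value.
The intervention arm additionally pays a one-off single cost at cycle
0. Everything is expressed per cohort unit per cycle; scaling to a
population is a reporting-time multiplication, which keeps the engine
scale-free and makes results comparable across cohort sizes.

Monetary amounts are in "MU" (monetary units), an opaque currency
label: nothing in the engine depends on what one MU is, only on ratios
of MU to effect units.

## Parameters that matter

* **Transition matrices** (per arm): per-cycle probabilities; rows must
  sum to 1 within an absolute tolerance of 1e-9 and are then
  renormalized exactly (each row divided by its sum). The tolerance
  absorbs decimal round-off from CSV/YAML round-tripping; the exact
  renormalization guarantees bit-level mass conservation downstream.
* **Initial distribution**: proportions on the simplex, same tolerance
  and renormalization.
* **Costs** (per arm, MU): `single` (once, cycle 0), `periodic`
  (per cycle, state-independent), `indirect` (per cycle, per state).
  All nonnegative.
* **Effects** (per arm, per state, per cycle): any finite values in a
  declared effect unit. The two arms may differ, even though the
  packaged case study sets them equal.
* **Horizon**: number of cycles, a positive integer. **Cycle length**
  is a label (e.g. "1 year"); the engine works in cycles.
* **WTP**: willingness to pay, MU per effect unit, the slope of the
  acceptance threshold on the cost-effectiveness plane.
* **Discount rate** (default 0): when r > 0, cycle-t costs and effects
  are multiplied by (1+r)^-t. The default is zero so that undiscounted
  worked examples reproduce exactly; the option exists because
  discounting is standard practice in health economics.

## Accrual conventions and numerical choices

Whether cycle 0 accrues the initial distribution's running costs and
effects is a genuine modelling choice; published cohort analyses use
both conventions and rarely say which. `markovce` defaults to
*inclusive* accrual (`accrue_cycle_zero = TRUE`): it makes a horizon of
0 meaningful (the model then reports the status quo cost of one cycle)
and treats the first observed cycle symmetrically with later ones. The
exclusive convention is one flag away, and for the packaged case study
the accept/reject conclusions are identical under both (the 5-year ICER
moves from about 512 to about 525 MU per effect unit, inside the same
400–700 bracket).

Other numerical decisions:

* Accumulation is plain left-to-right summation over cycles; with at
  most a few hundred cycles and well-scaled inputs there is no need for
  compensated summation.
* There is no half-cycle correction: costs and effects count the full
  cycle's expectation at the distribution holding at the start of the
  cycle. This matches plain per-cycle accrual; analysts wanting
  mid-cycle timing corrections should apply them downstream.
* ICER with a zero incremental effect is reported as `NA` (undefined),
  never ±Inf, and the decision falls back to axis rules: effect-neutral
  results are accepted iff they save money; cost-neutral results iff
  they do not lose effect.
* Quadrant classification treats |Δ| below 1e-12 times the series
  scale as zero, so floating-point dust cannot flip a result between
  "axis" and a quadrant.
* Exhaustive validation: `validate_model()` reports *all* violations in
  one error (each offending row named with its sum), because model
  configs are edited by hand and fixing one error per run is hostile.

## The decision rule

On the plane (x = ΔE, y = ΔC): south-east means the intervention is
cheaper and more effective — dominant, accepted at any WTP; north-west
is the mirror image — dominated, always rejected. North-east (more
effective, more costly) accepts iff ICER ≤ WTP; south-west (cheaper,
less effective) accepts iff ICER ≥ WTP, i.e. each forgone effect unit
saves more than the payer's valuation of it. Off the axes these rules
coincide with the sign of the net monetary benefit WTP·ΔE − ΔC, which
the test suite verifies over a thousand random models.

## Estimating inputs

`estimate_transitions()` turns a one-cycle transition count table into
row-proportion (maximum-likelihood) probabilities. No smoothing is
applied by default — a printed count table must reproduce its printed
probabilities digit for digit, and structural zeros (transitions the
system forbids) must stay exactly zero. An add-alpha option exists for
genuinely sparse observed data. Rows without observations are an error
naming the state, because silently imputing a row would fabricate
dynamics.

`effect_from_exposure()` maps a state's exposure level P ∈ [0, 100] to
an effect (100 − P)/100, the case study's "usefulness" score. It is one
pluggable mapping; the engine accepts any per-state effect vector.

## Scenarios and sweeps

Scenario analysis applies sparse, dotted-path overrides
(`intervention.costs.single = 50`) to a base model, re-validates, and
reruns. Paths mirror the YAML config schema so scenario files stay
declarative and diffable. `sweep_parameter()` generalizes this to a
one-way grid. Reverting an override reproduces the base result bit for
bit because the overridden model is rebuilt through the same
constructors.

## What the random-model generator emulates

`generate_fixture_model()` draws complete valid models deterministically
from a seed: transition rows uniform on the probability simplex
(normalized unit-rate gamma draws), initial distribution likewise,
exposures uniform on [0, 100], effects uniform on [0, 1], intervention
single cost uniform on [0, 1000] MU with periodic and indirect costs on
[0, 50] MU. These ranges bracket the case study's magnitudes and give
roughly balanced quadrant coverage on the plane, which is what the
property tests need (sign rules, antisymmetry, NMB agreement, mass
conservation).

What the generator does *not* emulate: real transition matrices are
sparse and diagonally dominant (units mostly stay put), costs are
correlated with states, and effects are monotone in exposure. A uniform
simplex draw has none of that structure. Passing property tests
therefore demonstrate the engine's algebraic correctness on arbitrary
valid inputs, not that any particular real-world parameterization is
plausible — plausibility is the analyst's job, supported by
validation.

## Problem sizes and verification

The test suite verifies the engine three independent ways: frozen
hand-computed values for the worked case study (single propagation
steps, five-year accruals, the ICER and its decision bracket); a naive
loop-based oracle re-deriving every series; and a 100,000-unit
multinomial microsimulation that must agree with the deterministic
trace within binomial 3-sigma per entry. Property tests run across
1,000 seeded random models (mass conservation, decision/NMB agreement,
arm-swap antisymmetry) and long-horizon checks propagate 1,000 cycles.
These sizes were chosen to make the checks statistically meaningful
while keeping the whole suite at desk scale — the full run takes about
a minute on one CPU.

## Known limitations

* Time-homogeneous transitions only; no tunnel states or
  cycle-dependent matrices.
* No half-cycle correction.
* No probabilistic sensitivity analysis (parameter distributions, ICER
  clouds, acceptability curves); `sweep_parameter()` covers one-way
  deterministic sensitivity only.
* Confidence intervals on estimated transition probabilities are out of
  scope; the estimator is the plain row-proportion MLE.
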