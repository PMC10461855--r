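---
title: "Coherent-feedback homeostats and background compensation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherent-feedback homeostats and background compensation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeostat)
```

# The control structure

All five networks in this package share a two-layer negative-feedback
architecture built from mass-action and Michaelis–Menten kinetics.

**Inner layer.** A controlled variable $A$ is regulated by a
manipulated variable $E$.  Integral control arises from *zero-order*
removal of the controller species: when a removal flux
$k \cdot E/(K_M + E)$ is saturated ($E \gg K_M$), the steady-state
condition of $E$'s rate equation no longer involves $E$ itself and
instead pins the (time-averaged) value of whatever drives $E$'s
production.  For the motif-2 family, $\dot E$-balance gives
$\langle A \rangle_{ss} = A_{set} = k_6/k_4$ regardless of the
perturbation — robust perfect adaptation.  If the loop oscillates, the
*time average* $\langle A\rangle(t) = \frac1t\int_0^t A\,dt'$ adapts
rather than $A$ itself.

**Outer layer.** A second pair of integral controllers, $I_1$
(outflow-type: active when $\langle E\rangle$ is above its set-point)
and $I_2$ (inflow-type: active below its set-point), holds
$\langle E\rangle$ inside the band
$[E_{set}^{I_2}, E_{set}^{I_1}]$.  Because $E$'s average is fixed, the
oscillator's frequency returns to its pre-perturbation value after a
step — frequency homeostasis.

**Coherent vs incoherent wiring.** The package's central contrast is
*where* the outer controllers act:

* **coherent feedback** — $I_1$ and $I_2$ feed back *directly through
  $A$* (an $I_2$-driven inflow to $A$, an $I_1$-driven removal of $A$).
  The compensating fluxes then absorb any constant background load on
  $A$, and the response to a given step (frequency profile, or the
  excursion $\Delta A$) becomes independent of the background.
* **incoherent feedback** — the same controllers feed back to a
  *precursor* $a$ of $A$ (`m2_incoherent_osc`).  Frequency homeostasis
  survives, but the background still attenuates the step response: the
  maximum post-step frequency falls monotonically with the background.

The five registered networks:

| name | layers | character |
|---|---|---|
| `m2_coherent_osc` | derepression inflow motif, zero-order removals of A | relaxation oscillator |
| `m8_coherent_osc` | outflow motif: A inhibits E production, E inhibits A removal | relaxation oscillator |
| `m2_firstorder`   | as m2 but all A-removals first order in A | non-oscillatory |
| `dual_e`          | two inflow controllers E1/E2; only E2 wrapped by I1/I2 | damped oscillations |
| `m2_incoherent_osc` | outer layer feeds a precursor of A | oscillator, *no* compensation |

Set-points are hand-derived ratios of rate constants (e.g.
`setpoints(hm_model("dual_e"))` gives $A_{set}^{E_1} = k_6/k_4 = 2.1$
and $A_{set}^{E_2} = k_{12}/k_{13} = 2.0$); the full Michaelis forms
are always what is integrated — the zero-order approximation enters
only these analytic calculators, never the simulation.

# Parameters that matter

All quantities are in arbitrary units (au); rate constants are named
$k_i$ regardless of kinetic role.  The behaviour-defining choices:

* **Michaelis constants of order $10^{-6}$–$10^{-4}$** make the
  zero-order saturation sharp.  They also make the systems stiff near
  zero concentrations, which dictates the solver tolerances below.
* **Set-point ordering.**  For a cooperating inflow/outflow pair the
  inflow controller's set-point must lie *below* the outflow
  controller's ($E_{set}^{I_2} < E_{set}^{I_1}$, e.g. 4.99 vs 5.0 for
  the m2 oscillator).  `setpoints()` warns when the ordering is
  violated or exactly tied — a warning rather than an error, because
  mis-ordered ("windup") regimes are legitimate objects of study.  The
  motif-8 reference set reverses the rule by design ($10 < 50$); its
  controller pair drifts slowly and deliberately, and the package does
  not apply the m2 ordering check to it.
* **m8 inhibition constant `k10 = 2.5`.**  In the motif-8 scheme `k10`
  is the constant with which $A$ inhibits production of the
  intermediate $e$.  The value 2.5 makes the bundled reference initial
  state lie exactly on the $e$-nullcline (the state is a snapshot taken
  at an $e$-extremum of the attractor); at this value the scheme
  oscillates with period $\approx 3.2$ au as the reference protocols
  require, whereas values of order $10^3$ abolish the oscillation
  entirely.
* **`k1 = 0` in the first-order scheme.**  The first-order variant's
  $A$-equation admits a constant basal inflow `k1`; its reference value
  is 0, under which the bundled initial state is an exact steady state.
  Users can set it freely.

# Pre-step states: families, not points

A subtlety that shapes every background-comparison protocol: the
non-oscillatory schemes do **not** have a unique pre-step steady state.
With both outer removals saturated, $I_1$ and $I_2$ are constrained
only by the flux balance of $A$, leaving a one-parameter family
(coordinatised here by $I_2$).  In the dual-controller scheme the
$I$-pair additionally drifts at $\dot I_2 = k_{18}E_2 - k_{19} =
+0.01$ by construction, sliding along that family forever.

The response amplitude $\Delta A$ depends on the family coordinate,
because the linearised removal slope of $A$ is
$k_{g3} I_1 + k_2 + k_{10}$ and the balance ties $I_1$ to $I_2$ and the
background.  Comparing backgrounds at *different* $I_2$ therefore
confounds the comparison.  `steady_state()` constructs the phase-1
state analytically at a **common $I_2$ reference** for every
background (defaults: $2.8492\times10^4$ for `m2_firstorder`, 2088.8
for `dual_e`, matching the bundled reference states).  With that
construction the step-response profiles at backgrounds 0 and 1024
superimpose to about $10^{-6}$ of the excursion amplitude.

For the oscillators no closed form exists; `pre_equilibrate()` instead
integrates a burn-in until the per-cycle period stabilises to 0.1%.
Backgrounds with bundled attractor snapshots start from those.  Note
that a *common-seed* burn-in across a 2048-fold background range is
not an option for the m2 oscillator: a state adapted to one background
is so far from another background's basin that the controllers wind up
catastrophically before re-adapting.

# Measurement protocols

**Cumulative averages and their asymptotes.**  `running_average()`
computes $\langle X\rangle(t)$ by cumulative trapezoid quadrature from
a configurable origin (default: the run start, so the statistic is the
plain normalised integral).  Cumulative averages converge like $1/t$
— far too slowly to read an asymptote off a finite run (at $t=10^4$
the m2 oscillator's $\langle E\rangle$ still sits 1% below its limit).
`asymptotic_average()` therefore offers a *cycle-aligned* estimator:
the trapezoid mean of the signal over the last $n$ complete detected
cycles, which for a periodic orbit equals the exact limit of the
cumulative average.  For non-oscillatory signals it falls back to the
tail value with a convergence flag (relative change below 0.1% over
the final 10% of the horizon).

**Cycle detection.**  `detect_cycles()` finds local maxima, refines
each peak time by three-point parabolic interpolation, and discards
peaks whose topographic prominence (height above the lowest saddle
separating them from higher ground) is below 1% of the running
peak-to-trough range.  Period = successive peak-time differences;
frequency = inverse period, the per-cycle reading used throughout.  No
spectral estimation is involved.  Fewer than two qualifying peaks
yields an empty table, which downstream operators interpret as a
non-oscillatory regime.

**Maximum post-step frequency.**  The statistic whose background
invariance defines compensation for oscillators:
`max_post_step_frequency()` takes the largest per-cycle frequency
among cycles starting at or after the step.  One artefact matters: the
result depends on the *oscillation phase at which the step lands* (for
a weak step, by $\pm 4\%$), because the first post-step cycle
inherits the truncated pre-step phase.  Since the phase at a fixed
step time is essentially arbitrary — the pre-step period is the same
8.33 au at every background, but the initial phases are not aligned —
sweeps can marginalise it out: with `phase_average = n`, the step is
applied at $n$ offsets spanning one pre-step cycle and the *median*
of the $n$ maxima is reported.  The median (not the mean) is used
because one offset per cycle — the step landing just before an
imminent peak — produces a truncated-cycle outlier about 10% high.
With `phase_average = 8` the m2 oscillator's compensation spreads
settle at 0.5–0.8% across backgrounds 0–2048; single-phase runs at the
caption times remain the default everywhere else.

**Response amplitude.**  `delta_A()` is the maximal absolute post-step
deviation from the pre-step steady value
($\max_{t \ge t_{step}} |A(t) - A_{ref}|$).  The construction is
configurable via the `reference` argument, since a peak-to-peak
variant is conceivable; the deviation-from-reference form is the one
consistent with background-invariant parallel response lines.  An
unsettled pre-step state triggers a warning, not an error.

**Compensation verdict.**  `check_background_compensation()` computes,
per step value, the relative spread $(\max - \min)/\text{mean}$ of the
statistic across backgrounds and passes when all spreads are below the
tolerance (default 1%; in a deterministic ODE pipeline, disagreement
beyond integration error is genuine non-compensation).  The verdict is
always computed on linear values — log axes can make an uncompensated
family look deceptively parallel, which is itself one of the points
the incoherent control makes.

# Numerical choices

* **Solver**: `deSolve::lsoda` (automatic stiff/non-stiff switching)
  with compiled C right-hand sides; `rtol = 1e-8`, `atol = 1e-10`.
  Looser tolerances visibly distort the relaxation-oscillation
  periods.  Halving the tolerances changes trajectories by less than
  $10^{-6}$ of the signal scale (tested).
* **Schedules**: integration is segmented at every breakpoint of the
  piecewise-constant parameter schedules, with a solver restart per
  segment — stiff multistep interpolants handle parameter jumps
  poorly.  A straight-through mode exists for testing and agrees with
  the segmented integration to $10^{-5}$.
* **Output grids**: 0.01 au for oscillatory models (periods are order
  1–10 au), 0.1 au for non-oscillatory ones; always
  solver-interpolated.
* **Negativity**: states are concentrations; excursions down to
  $-10^{-6}$ au (the legitimate undershoot scale of lsoda on these
  stiff cycles, whose troughs reach $\sim 10^{-6}$) are clipped to zero
  and counted in the trajectory diagnostics, anything worse aborts.
* **Determinism**: nothing in the simulation pipeline is random; seeds
  appear only in the synthetic-signal fixture generator.

# What the fixtures emulate — and what they do not

`make_signal()` produces constants, ramps, sinusoids, damped sinusoids
and step-relaxations with programmed ground truth (period, excursion,
mean), plus optional seeded Gaussian noise; `make_sweep_fixture()`
produces compensated or programmed-degradation sweep tables.  These
validate the *analysis operators* independently of the ODE engine:
quadrature accuracy, period recovery to 0.5%, excursion recovery,
verdict arithmetic.  They deliberately do **not** mimic any network's
waveform shape — relaxation-oscillation asymmetry, amplitude drift, or
the controller-branch structure discussed above — so a passing fixture
suite says the instruments are calibrated, not that the models behave;
the model-level claims are tested by simulating the networks
themselves.

# Known limitations

* The zero-order idealisation is only approximate at the reference
  constants.  The clearest case: for the motif-8 scheme the analytic
  long-time average $\langle 1/(k_{10}+A)\rangle \to k_7/(k_6 k_{10})$
  assumes $E$'s removal stays saturated, but $E$ dips below its
  Michaelis constant during each relaxation crash, and the converged
  empirical average sits about 6% below the prediction.  The exact
  stationarity identity
  $\langle k_6 k_{10}/(k_{10}+A)\rangle = \langle k_7 E/(k_8+E)\rangle$
  holds to better than 1% (tested), isolating the discrepancy to the
  idealisation.  Compensation spreads of a few tenths of a percent
  (rather than zero) have the same origin.
* Background compensation degrades for weak steps measured at a single
  arbitrary phase; use the phase-marginalised protocol when comparing
  backgrounds.
* No stochastic simulation, no event detection beyond schedule
  breakpoints, no fitting of the retinal model to recordings, and no
  $\alpha \ne 1$ version of the background-shift identity (it is an
  algebraic property of the $\alpha = 1$ law).

# Problem sizes used in the checks

The bundled test suite and the acceptance script run desk-scale
versions of the reference protocols: the m2 set-point run to
$t = 2000$ au ($2\times10^5$ output points); the first-order sweep as
the full published 9 steps × 6 backgrounds; the oscillator
compensation sweeps with 4 backgrounds (m2: 0, 16, 256, 2048; steps
1→2 … 1→10, phase-marginalised over 8 offsets) and 3 backgrounds × 3
steps (m8); the incoherent control with its full published 4 × 9 grid.
These sizes were chosen so that each check completes in seconds while
spanning the full background range of the corresponding published
protocol.
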