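---
title: "A multi-compartment model of ventilation energetics and strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-compartment model of ventilation energetics and strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventstrain)
```

## The model and its assumptions

`ventstrain` treats the passively ventilated lung as a linear RC circuit: a
rigid, non-storing airway tree whose internal edges carry shared proximal
resistances and whose leaves are elastic compartments, each with a fixed
resistance R (cmH2O·s/l), a fixed linear compliance C (l/cmH2O) and a
resting (unstressed) volume V_rest (l). The model deliberately assumes:

- **Linearity.** R and C are constant over the breath; there is no
  viscoelastance, no tidal opening/closure, no stress risers, no nonlinear
  (turbulent) resistance, and no conversion to SI energy units.
- **No inter-compartment mechanical coupling.** Expansion of one compartment
  does not change the functional compliance of its neighbours; compartments
  interact only through the airway network's flow partitioning.
- **Passive ventilation.** No patient effort, triggering or cycling logic;
  inspiration ends at exactly `ti`, when the expiratory valve opens to a
  PEEP source. The PEEP source is ideal (instantaneous, no expiratory valve
  resistance) — a modelling choice, since the alternative (an explicit
  expiratory resistance) is not identifiable from the quantities the model
  is meant to reproduce.
- **Spherical-analog strain.** Strain is the volume-linear expansion ratio
  `1 + (V + C·P_ex)/V_rest`, not a cube-root radius ratio; local geometric
  stress concentration is out of scope.

Writing `v_i` for the *absolute* elastic volume of compartment *i* (so its
alveolar pressure is `v_i/C_i`), Kirchhoff conservation at each internal
node plus an Ohm-analog drop `R·Q` on each edge give a linear algebraic
system for the node pressures. Eliminating it yields the compartmental ODE
`dv/dt = A v + b u(t)` with constant `A`, `b` for each boundary kind
(`u` = airway flow for CF/DF/SF, `u` = airway pressure for CP and for
expiration). The state variable is `v`, not the above-residual volume `V`
the reported tables use: cycling and auto-PEEP are then well defined without
circularity, and `V(t) = v(t) − v*` and `P_ex = v*/C` are derived at
reporting time from the steady-state residual `v*`.

Reported per-compartment quantities over inspiration are the intracycle
elastic power `ICP_elastic = Q (V/C + P_ex)`, its cumulative integral
`A(t)`, strain, strain rate and the cycle maximum of strain, `S_max`. The
driving (`Q V/C`) and total (`Q (V/C + P_ex + R_path Q)`) power components
are available as optional outputs; only the elastic component feeds strain.

## The two strain-rate forms

The energy-form strain rate
`ICP/(V_rest · sqrt(2CA + C²P_ex²))` simplifies, along any trajectory of the
linear compartment, to `Q/(C·V_rest)`; the time derivative of the strain
definition itself is `Q/V_rest`. The two differ by the constant factor
`1/C`, i.e. the energy form is not dimensionally consistent with the strain
it accompanies. The package does not silently correct either: both are
implemented (`strain_rate_printed()`, `strain_rate_consistent()`), the
volume-consistent `Q/V_rest` is the default in summaries, and their ratio
`1/C` is asserted in the test suite. `"ICP"` in the energy form is taken to
mean the same compartment's elastic power, the only component the strain
derivation defines.

## Network topology

The serial-backbone default — airway opening −R0− n1 −R1− n2 −R2− n3 −R3−
n4, with branches n1→A, n2→B, n3→C and n4→{D, E} — is one consistent
reading of the compartment diagram this model family uses; the exact wiring
is not uniquely determined by the published description, so the topology is
fully user-configurable (any rooted tree whose leaves are the compartments)
through the scenario file, and alternative readings are one config edit
away. Two published values of the second shared resistance circulate (1 and
3); `baseline_scenario(shared = "alt")` selects the latter, 1 is the
default. One visible consequence of the wiring ambiguity: calibrating the
constant-pressure mode to the 1.7 l constant-flow breath gives `P_set` =
13.03 cmH2O on the default reading and 14.20 on the `alt` variant,
bracketing the conventionally quoted 13.75.

## Numerical choices

- **Integration.** Within a phase the system is linear and can be stiff
  (time constants from ~0.16 s to ~0.4 s against a 1 ms reporting grid), so
  phases are integrated with `deSolve::lsoda` at rtol 1e−9 / atol 1e−12 l;
  the output grid (default Δt = 1 ms) does not limit accuracy.
- **Steady state.** The cycle map is affine (`v_end = M v0 + c`); `M` and
  `c` are identified exactly from n+1 cycle simulations (zero state plus
  unit basis states) and the fixed point solved directly, rather than
  iterating breaths open-endedly. A guard rejects a non-contractive map
  (impossible for a passive RC network), and a confirmation cycle must
  return to the fixed point within 1e−9 l. On the baseline scenario the
  confirmation residual is ~1e−12 l and the fixed point agrees with
  200-cycle brute-force iteration to ~1e−12 l.
- **Cumulative energy.** `A(t)` is integrated with a cumulative Simpson rule
  on the uniform part of the grid (trapezoid on any irregular tail, or on
  request). Fourth-order quadrature matters here: constant-pressure
  inspiration begins with a fast flow transient, and trapezoid on the 1 ms
  grid leaves ~2e−5 relative error in the energy–volume identity
  `2CA + C²P_ex² = (V + C·P_ex)²`, versus ~2e−8 for Simpson.
- **Maximal strain** is the maximum over the whole cycle, not the value at
  end-inspiration: slow compartments can keep filling briefly into
  expiration (pendelluft), and on the baseline scenario compartments B and C
  indeed peak ~20–30 ms after `ti`. Sweep tables therefore store both the
  end-inspiratory volume (`V_T_comp`) and the peak volume (`v_peak`);
  `S_max` re-derives exactly from `v_peak`.
- **Degenerate inputs.** Negative elastic volume aborts integration (the
  linear model is being used outside its domain); values within −1e−9 l of
  zero are clamped. Zero radicand in the printed strain-rate form (t = 0
  with P_ex = 0) is reported as a singular point rather than patched.
- **CP calibration** solves for `P_set` by bracketing root search on the
  *periodic steady-state* inspired volume (monotone in `P_set`), not the
  first breath, because the strain formulas use steady-state `P_ex`; the
  achieved volume must match the target within 1e−4 l.

## Experiment design choices

- **Mode comparison at matched tidal volume.** All profiles are compared at
  the same `V_T` and `ti` (flow amplitudes in closed form: `Q_aw = V_T/ti`,
  `Q_max = 2V_T/ti` for the triangle, `π V_T/2ti` for the half-sine; CP by
  calibration). The decelerating profile is a strict triangle reaching zero
  flow at `ti`; the sinusoidal profile is a half-period sine, zero at both
  ends — "sinusoidal" alone does not fix the phase, so this is a documented
  package decision. CP is an ideal pressure source with no rise-time ramp.
- **PEEP sweep: what is held fixed.** Flow modes hold their set amplitude
  (hence `V_T`) while CP holds `P_set` (so its `V_T` shrinks as PEEP rises),
  mirroring how each mode is set clinically. The published description does
  not state its choice; this one is therefore prominent in the function
  documentation. Grid default: 0–12.75 cmH2O in 0.25 steps. A consequence
  worth knowing: with a fixed flow amplitude each compartment's `S_max`
  gains exactly `C·ΔPEEP` (the affine circuit shifts bodily with PEEP),
  whereas CP's gains are smaller and ranked differently across
  compartments — the sense in which PEEP "distributes differently" under
  pressure control. On this topology the *ranking* of `S_max` itself at a
  fixed PEEP is the same in all four modes; the mode differences appear in
  the PEEP-sensitivities, not the standings.
- **Tidal-volume × peak-flow grid.** Each cell sets the inspiratory time the
  profile requires (`ti = V_T/Q`, `2V_T/Q_max`, `π V_T/2Q_max`); cells with
  `ti ≥ ttot` are marked infeasible, and cells where any compartment's
  `P_ex` exceeds set PEEP by more than 0.1 cmH2O are flagged as auto-PEEP
  cells. The documented superlinearity of `S_max` in `V_T` is an auto-PEEP
  phenomenon: it appears where longer inspirations squeeze expiration below
  the slow compartments' time constants (e.g. `Q_max` ≤ 2 l/s with `V_T` up
  to 1.6 l on the baseline), and is absent when expiration stays long.
- **Resting-volume sweep.** `V_rest` enters only the strain mapping, never
  the circuit, so the steady state is computed once per mode and rescaled
  across the 0.2–1.2 l grid; `(S_max − 1)·V_rest` is exactly constant. The
  heterogeneous preset `vrest_map_preset()` (A 0.5, B 0.75, C 0.95, D 1.2,
  E 1.0 l) is a synthetic, documented assignment under which the
  high-compliance compartment A attains the highest maximal strain and the
  high-resistance compartment D the lowest; no canonical values exist.

## What the baseline scenario does and does not emulate

The built-in scenario (five compartments spanning compliances 0.02–0.08
l/cmH2O and resistances 1–15 cmH2O·s/l, PEEP 2 cmH2O, 1 s inspiration in a
3 s cycle, 1.7 l breath) is a caricature of a mechanically heterogeneous,
acutely injured lung: it mixes fast/compliant and slow/stiff units so that
flow partitioning, gas trapping and pendelluft are all visible. Passing the
test suite on it demonstrates internal consistency of the circuit solver,
steady-state logic and energetics, and reproduction of the qualitative
behaviours above — not fidelity to any patient: real lungs have nonlinear,
time-varying, coupled mechanics, and this model's strain analogs are
macromechanical proxies, not tissue-level predictions.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated inputs:
the baseline scenario at Δt = 1 ms (3001 samples/cycle), full PEEP sweeps
(52 points × 4 modes), V_rest sweeps (21 points), tidal-volume grids of
~13 × 2 cells in the auto-PEEP regime, 200-cycle iteration cross-checks and
20–25 randomized network probes. The complete suite runs in well under a
minute on one core.

## Known limitations

Beyond the assumptions listed above: tidal volumes are not bounded by any
physiologic ceiling (the linear compartment inflates indefinitely);
calibration and sweeps assume the passive, contractive cycle map (always
true for positive R, C); and no optimisation over flow profiles is included
— the package maps the strain landscape, it does not search it.
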