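---
title: "Modelling pulsatile sigma-B activation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pulsatile sigma-B activation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigbpulse)
```

## The circuit and its chemical reaction network

The general stress response of *Bacillus subtilis* is gated by the
alternative sigma factor sigma-B through a partner-switching cycle. The
anti-sigma factor RsbW (here `W`) dimerises and the dimer both sequesters
sigma-B and phosphorylates the anti-anti-sigma factor RsbV (`V`).
Unphosphorylated V attacks the W2-sigma-B complex and displaces sigma-B
(partner switching); phosphorylated V (`VP`) is recycled by a
stress-controlled phosphatase `P` through a Michaelis-type complex `PVP`.
Stress raises the phosphatase level, which tilts the V phosphorylation
balance, frees sigma-B, and activates the sigma-B operon -- which in turn
produces more sigma-B, W and V, closing a mixed feedback loop.

`core_network()` builds this as a mass-action chemical reaction network with
10 species and 27 reactions: 3 operon production reactions, W dimerisation
(propensity `kBw*[W]^2/2`; `kBw*W*(W-1)/2` on molecule counts), 4 binding
reactions, the 2 partner-switching exchanges, 5 dissociations, 2
phosphorylations (`kK1`, `kK2`), 1 dephosphorylation (`kP`), and first-order
degradation/dilution of the 9 non-phosphatase-conserving species.
Degradation of the `PVP` complex releases `P`, so every reaction conserves
total phosphatase `[P] + [PVP]` exactly -- a property asserted columnwise on
the stoichiometry matrix in the test suite and used to cross-check every
integrator.

`modified_network()` adds an inactive phosphatase state `PI` and three
switching reactions (`PI -> P`, `P -> PI`, `PVP -> PI + VP`, all at rate
`eta_freq`). Deterministically this changes nothing about the total
phosphatase budget; stochastically it adds an upstream noise channel whose
amplitude is scaled separately (`eta_amp`) from the core circuit noise
(`eta`), and whose correlation time is set by `1/eta_freq`. The stress step
in the modified model raises `P` and `PI` together, so the post-stress
total is twice the nominal stress level with half active on average.

## The operon production rate

The sigma-B operon activity enters as a saturating function `f([sigB])`
multiplying the production of sigma-B (weight 1), W (`lambda_W = 4`) and V
(`lambda_V = 4.5`). Two algebraically inequivalent readings of this curve
are in circulation for this model family:

* `"ratio"` (package default): `f(s) = v0 * (1 + F*s) / (K + s)`;
* `"offset"`: `f(s) = v0 * (1 + F*s/(K + s))`, with basal rate exactly `v0`.

Both are implemented (`production_form` argument of the network builders).
The default was chosen by validation against the circuit's published
steady-state stability structure rather than by typography: under the ratio
form the deterministic model reproduces, with no parameter adjustment,
(i) a fully stable stress branch at canonical parameters over
`p_stress` in 0.1--10 uM, (ii) an instability window in `kK2` alone
(roughly 9--18 per hour at `p_stress = 0.8` uM, with the canonical
`kK2 = 36` stable), (iii) quiescent steady states at
`(kK2, eta) = (7, 0.025)` for `p_stress` up to about 0.3 uM with a
stable--unstable--stable sequence further up the stress axis, and (iv) the
noise-triggered single-pulse/stochastic-pulsing boundary within about 10%
of its published stress level. Under the offset form the same parameter set
oscillates deterministically where the published model is quiescent. The
offset form remains available for sensitivity analyses.

## Simulation engines

Three engines share one compiled network representation:

* **ODE** (`simulate_ode()`): the deterministic reaction-rate equations.
* **CLE** (`simulate_cle()`): the chemical Langevin equation
  `dx_i = sum_j v_ij a_j dt + sum_j s_j v_ij sqrt(|a_j|) dW_j`, one
  independent Wiener increment per reaction per step, with `s_j = eta` for
  core reactions and `s_j = eta_amp` for the upstream switching reactions.
* **SSA** (`simulate_ssa()`): Gillespie's direct method on integer molecule
  counts, using the same numerical rate values read in molecule units
  (no volume conversion is attempted between the two unit systems).

The ODE and CLE paths use the same fixed-step, drift-implicit,
diffusion-explicit Euler--Maruyama scheme: each step solves
`y = x + dt*S*a(y) + d` by damped modified Newton with the analytic drift
Jacobian (tolerance `1e-10` on the max-norm residual, at most 20
iterations, one Jacobian factorisation per step refreshed if the iteration
stalls, recursive step-halving as a fallback). With the noise amplitudes at
zero the CLE path therefore *is* the ODE path, to solver tolerance -- a
contract the tests assert at `1e-6` in the sup norm.

Numerical conventions follow the chemical-Langevin standard for
non-negativity: the arguments of the square roots in the noise term are
absolute-valued, species are allowed to dip (slightly) negative under
noise, and nothing is clamped except when handing states to the
strict-mode propensity evaluator or the count-based SSA. The Newton
predictor is the current state shifted by the noise increment; an explicit
drift predictor is deliberately avoided because it overshoots at the stiff
stress onset, where phosphatase--VP binding relaxes on a seconds timescale.

**Step size.** The default is `dt = 0.001` h with trajectory sampling every
0.01 h. The noise-free path converges at first order (halving `dt` halves
the path difference; the tests assert the empirical order), and the
sup-norm difference between successive refinements is dominated by the
fast binding boundary layer at stress onset while the sigma-B trajectory
itself changes by less than 0.01 uM. More importantly, the discrete-time
CLE map is *unstable* for too-large steps at high noise: the bilinear
propensities make the noise effectively multiplicative, and at
`eta >= 0.05` paths at `dt = 0.005` h can run away through alternating-sign
excursions. `dt = 0.001` integrates all noise levels used in the shipped
experiments (`eta <= 0.04`) stably; high-noise ensembles
(`eta` around 0.06) use `dt = 5e-4`. Beyond `eta` around 0.1 occasional
divergence appears genuine to this noise formulation rather than a step
artefact (it persists under further refinement), which is consistent with
behaviour becoming noise-dominated at large amplitudes; such runs abort
loudly and scans record the failure per cell.

**Initial condition and burn-in.** Runs start 10 h before stress with every
species at zero except free phosphatase at `p_init` (both pools in the
modified model) and relax through the burn-in; `init_mode = "steady"`
starts at the deterministic pre-stress steady state instead. The burn-in
duration is part of the protocol (`stress_protocol()`), and the stress step
falls exactly on a grid point, with the stored sample at the stress time
reflecting the post-stress state.

**Seeding.** `simulate_ensemble()` gives member `i` the seed
`base_seed + i - 1`; all Wiener increments are drawn in fixed reaction
order, so a seed pins the full path bit-for-bit and members are
independent of evaluation order. Scans derive per-cell seed blocks from
the root seed and the cell index so any cell can be reproduced in
isolation.

## Behaviour measures

Each post-stress trajectory is split into a transient phase (0--5 h) and an
asymptotic phase (5--200 h); pre-stress samples are always excluded.
Activity is free `[sigB]` by default (total sigma-B, adding the sequestered
`W2sigB` pool, is selectable). From the three phase statistics --
transient maximum, asymptotic maximum, asymptotic mean -- two dimensionless
magnitudes are formed per trajectory:

* single response pulse: `M_srp` = transient max / asymptotic max;
* stochastic pulsing: `M_sp` = asymptotic max / asymptotic mean.

Dividing the transient pulse by the asymptotic *maximum* penalises the
single-pulse score whenever asymptotic pulses occur, so the two measures
cannot both be large. A constant trace scores 1 on both; a clean
oscillation with minimum near zero scores about 2 on `M_sp`; irregular
pulsing drives `M_sp` into the tens because rare tall pulses dominate the
maximum while the mean stays low. Ensemble scores are means of the
per-trajectory ratios (`n` between 50 and 200 in the shipped experiments;
the mean-of-ratios convention is asserted in the tests). Denominators
below `1e-12` define the measure as 1 (no behaviour); Langevin
trajectories never reach this guard in practice.

The excess magnitudes `M*_srp = max(M_srp - M_sp, 0)` (and symmetrically)
express by how much one behaviour surpasses the other; the equality case
maps to `(0, 0)`, so `M*_srp * M*_sp = 0` identically. Along a parameter
grid these feed two distinctness statistics. With `I_srp`, `I_sp` the
integrals of the excess magnitudes and `I_max` the integral of their
pointwise maximum:

* dual distinctness `D = 2 * I_srp * I_sp / I_max` -- large only when the
  sweep elicits *both* behaviours, each distinctly somewhere;
* single distinctness `D_srp = I_srp^2 / I_max` (and `D_sp`) -- favouring
  sweeps where one behaviour is prominent in absolute terms.

An alternative area form replaces the denominator by
`A_srp + A_sp + A_srp_sp`, where `A_srp_sp` is the area below both raw
magnitude curves. The two published forms are not algebraically identical
(they differ by the factor 2 and the shared-area term), so both are
computed and returned side by side; the ratio form is the default and
neither is guaranteed to stay below 1 for unbounded magnitudes -- the value
is reported as computed, not clipped. Integrals use the trapezoidal rule
on the stated grid, with a plain grid-sum variant selectable.

The sensitivity of a magnitude to a parameter sampled at `n` grid points is
`C = (n - 1) * sum (M[i+1] - M[i])^2`: the `(n - 1)` factor removes the
grid-density bias (a linear rise by `c` scores `c^2` for any `n`), and
squaring the jumps emphasises switch-like responses over gradual drift.

## Response classification

`classify_response()` maps an ensemble to one of `no_response`,
`single_pulse`, `stochastic_pulsing`, `oscillation`, `sustained_activity`.
The inputs are the ensemble-mean magnitudes, the asymptotic mean relative
to the pre-stress baseline, and a spectral concentration score (the
fraction of asymptotic-phase spectral power in the dominant frequency bin,
ignoring periods longer than an eighth of the window to suppress red-noise
drift; a limit cycle concentrates power in one bin, irregular pulsing
spreads it). Decision order: no response if neither phase rises above a
fold-change threshold over baseline; stochastic pulsing if `M_sp` is large;
oscillation if the spectral score is high with `M_sp` in the band a clean
oscillation produces and an elevated mean; sustained activity if the mean
is elevated with a flat profile; single pulse if `M_srp` is large;
otherwise no response with an ambiguity note. All thresholds are exposed
in `classifier_thresholds()` and are heuristics of this package, not
constants of the underlying model. At their defaults the classifier
recovers the five regimes of the stress-transition ladder (below) and the
idealised fixtures without tuning per case.

## Parameter scans and the stress scale

`sweep_scan()` runs seeded per-cell ensembles over factorial grids;
`max_over_parameter()` implements the reduction "best response achievable
by tuning the stress level" behind the noise-by-kinase-rate heatmaps;
`distinctness_profile()` produces the one-parameter magnitude profiles and
their distinctness statistics; `branch_scan()` sweeps deterministic steady
states (below). Desk-scale defaults (at most ~10 points per axis, `n` of
20--50 per cell) keep every shipped experiment in the minutes range on one
CPU; the same code runs publication-scale grids by raising `n` and the
grid density, changing nothing else.

One scale decision deserves emphasis. The upstream pathway is summarised by
`p_prod = p_stress * kP` (total RsbV dephosphorylation capacity) and
`p_frac = p_stress / kP`. Chemical-Langevin noise is intrinsic: its
relative size on a propensity `a` is `eta / sqrt(a)`. Stochastic pulsing
therefore requires the circuit to operate at micromolar concentrations --
at a hundred micromolar of phosphatase the relative noise is of order
`1e-3` and no pulsing regime exists along `p_prod` under either production
form (verified numerically; the transition there is a quiet-to-sustained
bistable jump). All `p_prod`-transition experiments in this package
consequently realise `p_prod` by varying `p_stress` at the canonical
dephosphorylation rate `kP = 180` per hour, keeping the circuit at the
micromolar scale where the five-regime phenomenology lives. At
`(kK2, eta) = (7, 0.025)` the shipped ladder
`p_prod = 18, 43.2, 57.6, 90, 270, 540` (uM/h) traverses no response,
single pulse, stochastic pulsing, oscillation, and sustained activity, and
the deterministic stress branch runs stable -> unstable (`p_stress` about
0.35--0.61 uM) -> stable in the same interval, mirroring the bifurcation
ordering of the transition.

## Steady states and stability

`find_steady_state()` solves the post-stress deterministic drift by damped
Newton in reduced coordinates: total phosphatase conservation makes the
raw Jacobian structurally singular, so `PVP` is eliminated through
`[P] + [PVP] = p_stress` and the conservation constraint is satisfied
exactly by construction. Warm starts come from the previous branch point
during sweeps, with a long relaxation of the drift as fallback guess;
residuals are accepted below `1e-9` (typically `1e-12`). `stability_at()`
classifies each state by the leading eigenvalue of the reduced analytic
Jacobian, with a `1e-8` marginal band; "unstable implies limit cycle" is
not asserted from eigenvalues alone -- the tests confirm bounded
oscillatory ODE trajectories at unstable points and convergence onto the
branch at stable ones. Periodic orbits themselves are not continued;
fold-adjacent regions are visible as branch jumps and reported through the
branch continuity diagnostics rather than traced.

## What the synthetic fixtures do and do not show

`reference_trace()` generates noise-free square pulses, raised cosines,
spike trains and constants with analytically known phase statistics. These
fix the measure implementations exactly (for example, a raised cosine with
minimum zero and an integer number of periods in the asymptotic window has
`M_sp = 2` up to the finite sampling of the grid), and they pin the
classifier's qualitative categories. They do not emulate the
heavy-tailed, irregular pulse statistics of the Langevin circuit -- pulse
shapes, refractory structure and amplitude distributions are properties of
the simulated model, not of the fixtures -- so passing fixture tests
validates the measurement code, while the simulation-level checks (ladder
classification, pulsing magnitudes, stability branches) validate the
model behaviour itself.

## Problem sizes used in the shipped checks

The automated checks run, per invocation: single trajectories of 210 h at
`dt = 0.001` h (`5e-4` for high-noise ensembles); ensembles of 10--100
members; a two-stage stress scan of about 14 points with 10--20 members
each; stability branches of 21--41 points; and a 50-fold scaled
molecule-count comparison of 50 Gillespie runs against the ODE. These
sizes were chosen so the full suite completes in minutes on a single CPU
while leaving the statistical contrasts being tested (pulsing magnitudes
in the tens, label transitions, stability windows) far above their
sampling noise; publication-scale ensembles (`n = 150` and dense grids)
are available through the `"paper"` presets of `run_experiment()`.

## Known limitations

* Intrinsic noise only: no cell-cycle, partitioning or extrinsic noise
  channels, and reaction channels are uncorrelated (dilution included).
* The discrete-time Langevin map diverges with noticeable probability for
  noise amplitudes beyond about 0.1 at feasible step sizes; results there
  should be treated as unreliable and are reported as failures, not
  silently retried.
* The single-pulse/stochastic-pulsing boundary location is sensitive to
  the production-form reading (about 10% in the stress level between the
  two parses); conclusions that depend on the exact boundary position
  should be checked under both forms.
* No periodic-orbit continuation: oscillation amplitudes and periods come
  from simulation, not from a boundary-value solver.
* Molecule-count (SSA) and concentration (ODE/CLE) modes share numerical
  parameter values by convention; no physical volume links the two unit
  systems.
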