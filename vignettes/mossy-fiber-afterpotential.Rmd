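---
title: "Methods: a pearl-chain cable model of the mossy-fiber after potential"
author: "pearlchain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a pearl-chain cable model of the mossy-fiber after potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pearlchain)
```

## The scientific question

Axonal action potentials are followed by an after potential lasting tens of
milliseconds that modulates excitability during repetitive firing. Two
candidate mechanisms dominate at hippocampal mossy-fiber boutons: fast
repolarization by voltage-gated K⁺ channels, which pulls the membrane toward
E_K and sets the early "breakpoint" of the after potential, and *capacitive
discharge* — charge delivered passively through the axon cable by the
upstream action potential, which relaxes with the slow passive time constant
of the loaded cable and dominates the late phase. The capacitive component is
nearly impossible to isolate experimentally (it requires simultaneous
recordings from two sites of one connecting axon plus spatially restricted
channel block), but it is trivial to isolate in a compartmental model by
deleting the voltage-gated conductances from a distal stretch of axon.
`pearlchain` implements that model and the complete set of in-silico
experiments around it.

## The model

### Morphology ("pearl chain")

A mossy fiber is idealized as a soma followed by ten repeats of a thin
axonal cylinder and a large *en passant* bouton in strict alternation
(soma → axon1 → bouton1 → … → axon10 → bouton10):

| element | diameter | length | count |
|---|---|---|---|
| soma   | 10 μm | 10 μm (cylinder, L = d) | 1 |
| axon   | 0.2 μm | 100 μm | 10 |
| bouton | 4 μm | 4 μm (cylinder, L = d) | 10 |

Soma and boutons are cylinders with length equal to diameter; only the
lateral membrane area π·d·L enters the electrical model, so this convention
fixes the membrane area each element exposes to the solver. Both chain ends
are sealed (zero axial flux); the sealed end produces the familiar amplitude
boost at the 10th bouton. Discretization is 1 segment per μm (axons: 100
segments each; boutons: 4; soma: 10; 1,050 segments in total), and the
discretization exactly conserves each section's membrane area.

### Passive properties and channels

Uniform passive parameters: Cm = 1 μF cm⁻², Rm = 10,000 Ω cm², Ri = 110 Ω
cm, leak reversal −81 mV (see *Resting potential* below). Voltage-gated Na⁺
(50 mS cm⁻² in axon and boutons, 10 mS cm⁻² in the soma; E_Na = +50 mV) and
K⁺ conductances (36 mS cm⁻² everywhere; E_K = −85 mV) follow
Hodgkin–Huxley-type kinetics: I_Na = g_Na·m³h·(V−E_Na), I_K =
g_K·n⁴·k_inact·(V−E_K), outward positive. `k_inact` is a KV1.4-like slow
inactivation gate (sigmoid steady state, V½ = −50.5 mV, slope 7 mV; constant
τ = 300 ms) applied *multiplicatively* on the n⁴ term; with τ in the hundreds
of milliseconds it is essentially inert during a single action potential and
matters only for repetitive activity. Setting `use_kinact = FALSE` clamps it
to 1 and recovers a pure n⁴ current.

### Gating kinetics and their calibration

The kinetics of mossy-fiber channels are not uniquely standardized, so the
package keeps them pluggable: a registry
(`register_gating_scheme()`) accepts any parameterization of a generalized
rate family in which each forward/backward rate of m, h and n is a
linoid, exponential or sigmoid function of voltage, plus a global rate
multiplier `phi` and voltage shift. A transcription of a published
mossy-fiber bouton scheme can be registered without touching the solver.

The shipped default (`hh_mf`) uses the classic squid rate *shapes* with two
physiological calibrations at the model's conductance densities:

1. **K⁺ activation shifted +20 mV.** Axonal Kv1-family channels half-activate
   far above the resting potential; with the unshifted squid n gate the model
   would carry a standing K⁺ conductance at −80 mV of roughly a third of the
   leak conductance, contaminating every passive property (membrane time
   constant ≈ 5.6 rather than ≈ 8 ms; steady-state length constant ≈ 159
   rather than ≈ 166 μm). After the shift the resting K⁺ open probability is
   < 10⁻⁴·36 mS cm⁻² and the "passive" measurements are genuinely passive.
2. **`phi` = 2.5.** The global rate multiplier is set so the simulated bouton
   action potential has a half-width of ≈ 0.8 ms, the room-temperature value
   for mossy-fiber boutons.

Quantities that depend on the action-potential waveform (the spatial decay of
the passive spike, its absolute amplitudes) inherit the residual uncertainty
of this calibration; the purely passive quantities (steady-state length
constant, relaxation time constants) do not. The unshifted squid scheme is
registered as `hh_squid` for comparison.

### Resting potential and leak retuning

With active conductances present, the resting potential is set by adjusting
the leak battery (`retune_leak_reversal()`), exactly as one retunes a model
in any simulation environment. Two modes exist:

* `per_segment` (default for protocols): solves the closed-form balance
  E_leak,i = V + (I_Na,ss + I_K,ss)/g_leak per segment, giving an exact,
  spatially uniform resting state — every segment sits at the requested
  potential indefinitely. Because the soma's Na⁺ density differs from the
  axon's, this produces (slightly) different leak reversals for soma and
  axon, which is the price of an exactly uniform rest.
* `global`: one uniform leak reversal, found by secant iteration on the
  settled potential at a chosen site (default bouton 10). This mirrors the
  single-battery convention of the reference model (whose printed value,
  −81 mV at a −80 mV rest, is the bundled default); the potential is then
  pinned only at the chosen site, with sub-millivolt to few-millivolt
  gradients elsewhere.

Protocols retune *after* applying their regional modifiers, so each simulated
configuration (knockout, E_K override, …) genuinely rests at the requested
potential and baselines are flat.

## Numerical scheme

The cable equation on the unbranched chain is a tridiagonal system

C_i dV_i/dt = −Σ_c g_c,i(V_i − E_c) − Σ_j g_ax,ij (V_i − V_j) + I_stim,i

with axial conductances from the series combination of half-segment
resistances 4·Ri·(L/2)/(π·d²). Time stepping is implicit — backward Euler by
default, Crank–Nicolson optionally — with the gates advanced in an
operator-split substep using the *exact* exponential update at the
start-of-step voltage (unconditionally stable; gates can never leave [0, 1]).
At the default dt = 5 μs the two schemes agree to well below every
measurement tolerance (halving dt changes the spike peak by < 0.05 mV;
`check_convergence()` reports this for any configuration). The solver runs in
compiled code; a 60-ms run of the 1,050-segment model takes well under a
second.

Currents are recorded per site with the convention that, at every recorded
instant, I_cap + I_Na + I_K + I_leak + I_axial − I_stim = 0 holds to solver
precision (for backward Euler the ionic/axial currents are evaluated at the
end-of-step voltage, for Crank–Nicolson at the mid-step voltage, so the
identity is exact for each scheme). The capacitive current is C·dV/dt; the
standalone helper `capacitive_current()` recomputes it from any voltage trace
with centered differences.

Everything is deterministic — there is no randomness anywhere in the
pipeline; identical inputs give bit-identical trace sets.

## Protocols

Each in-silico experiment is a declarative `protocol_spec` (serializable to
YAML and re-runnable bit-identically) over the base model:

* `protocol_passive_propagation()` — somatic stimulus (0.2 nA, 2 ms); Na⁺
  and K⁺ conductances deleted from the 8th axon through the chain end. The
  spike propagates normally to the 7th bouton and only its capacitive
  residue spreads further; peak amplitudes versus distance from the 7th
  bouton's distal end give the transient length constant.
* `protocol_steady_state_lambda()` — −4 pA, 500 ms into bouton 10 of the
  full model; steady-state deflections along the chain give the steady-state
  length constant, necessarily below the infinite-cable bound
  √(Rm·d/4Ri) ≈ 213 μm because the boutons load the thin cable.
* `protocol_voltage_dependency()` — full runs at −80/−90/−100 mV rest.
* `protocol_component_decomposition()` — control, gK removed from
  axon10+bouton10, gNa and gK removed; `decompose_components()` then forms
  V_mK = control − noK, V_mNa = noK − noNaK, V_cap = noNaK, whose sum
  reconstructs the control trace exactly by construction.
* `protocol_EK10_sweep()` — E_K overridden in axon10+bouton10 only
  (−65…−105 mV in 10-mV steps, bracketing rest), each with a passive
  companion run that must be — and is — bit-identical across E_K values.
* `protocol_step_family()` — standing ±pA steps (+1…−6) at bouton 10 with a
  propagated spike superimposed 50 ms after step onset.
* `protocol_Cm_sweep()` — the passive-propagation knockout repeated with the
  passive region's Cm at 0.5/1/2 μF cm⁻² (values chosen to bracket the
  default; the reference does not print them). Applying the override to the
  passive region only keeps the upstream spike generator identical across
  the sweep, so the effect of membrane capacitance on cable filtering is
  isolated.

Where the reference is silent on a protocol detail the package picks one
default and exposes it as an argument: stimulation site for the
voltage-dependency runs (soma by default; bouton-9 injection available),
step-family baseline (steps begin 50 ms before the spike-evoking stimulus).

## Measurement conventions

* **Amplitudes** are peak minus the mean over a pre-stimulus baseline window,
  per site, with per-segment baselines for spatial profiles (shift-invariant
  by construction).
* **Spatial decay** is a least-squares fit of A·exp(−x/λ) (log-linear
  initialization, Levenberg–Marquardt refinement); λ is exactly the 1/e
  distance. Non-decaying inputs are flagged rather than fitted.
* **Temporal relaxations** are fits of V∞ + B·exp(−(t−t₀)/τ). Both the
  step-response relaxation and the late after-potential phase are fitted over
  a *matched* window starting 10 ms after the perturbation (step onset or
  spike peak) and ending 40 ms after it. The first few milliseconds of either
  relaxation are multi-exponential — fast charge redistribution between the
  bouton and the adjacent cable — and a single-exponential fit anchored at
  the perturbation mixes those fast modes into τ. The fit-start sensitivity
  for the default model is substantial and is part of the result, not a
  nuisance: for the −4 pA step at bouton 10, τ rises from 5.8 ms (fit from
  onset) through 6.7 ms (+2 ms), 7.4 ms (+5 ms) to 7.9 ms (+10 ms) as the
  fast modes are excluded, approaching the isopotential bound Rm·Cm = 10 ms
  from below; the rms fit residual falls by ~30× between the +5 and +10 ms
  starts, which is why the +10 ms start is the default. With the matched
  convention the two time constants (step ≈ 7.9 ms, late after potential
  ≈ 7.3 ms) agree to better than 10%, which is the substance of the
  capacitive-discharge interpretation of the late phase.
* **After-potential level/polarity** is the mean of V − V_rest over 2–5 ms
  after the spike peak (inside the early phase that converges near E_K).
* **Current onsets** are 5% threshold crossings of the baseline-subtracted
  magnitude, linearly interpolated; `onset_delay()` reports
  onset(I_Na) − onset(I_cap). For spikes evoked directly at the recorded
  bouton a small residual lag (≈ 0.1–0.2 ms, the charge-to-threshold time of
  the stimulus) remains; "no delay" for direct stimulation is therefore
  assessed relative to the several-fold larger delay of propagated spikes.

## What the simulations show — and what they cannot

The simulator itself is the data generator of this study: all inputs are the
printed model parameters, and the traces it emits are the study's "data".
The defaults above *are* the study conditions. What passing tests demonstrate
is therefore internal: that this cable model, with these densities and
calibrated kinetics, reproduces the published passive decay lengths, time
constants, amplitudes and the polarity switch of the after potential. They
cannot demonstrate that real mossy fibers lack other slow conductances —
resurgent or persistent Na⁺ currents, Ih, T-type Ca²⁺, extracellular K⁺
accumulation and presynaptic autoreceptors are all deliberately absent from
the model, and at a −80 mV rest the model's after potential is accordingly
*hyperpolarizing* (early phase near E_K = −85 mV), whereas experimental
recordings show depolarizing after potentials; the model reproduces the
experimental waveform only at more negative resting potentials or more
positive E_K. That discrepancy is a finding, not a bug.

## Problem sizes and runtimes

All analyses run on the full 1,050-segment model at the reference dt = 5 μs:
the propagation runs simulate 60 ms (12,000 steps), the steady-state run
510 ms (102,000 steps), the step family 8 × 110 ms. The complete acceptance
recomputation takes ~30 s on one CPU; the test suite, which additionally
exercises analytic-oracle comparisons on single cables and the protocol
invariants, runs in about a minute.

## Known limitations

* The exact rate equations of the cited mossy-fiber gating model are not
  public in the reference; the shipped kinetics are a calibrated stand-in,
  and gating-dependent quantities carry the corresponding uncertainty.
* Unbranched chains only: no filopodia, no myelin, no axon collaterals.
* A single global temperature is implicit in `phi`; no Q10 machinery.
* The K⁺ slow-inactivation gate uses a constant time constant; its
  voltage dependence (known for recombinant KV1.4) is not modeled, which is
  inconsequential for single-spike protocols.
* `fit_spatial_decay` fits a single exponential; the true profile of a
  loaded periodic cable is only approximately exponential (the fit residual
  is reported so the approximation quality is visible).
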