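# pearlchain

Compartmental simulation of action-potential propagation and after
potentials in hippocampal mossy-fiber axons.

## The problem

After a propagating axonal action potential, the membrane potential of a
mossy-fiber bouton does not return immediately to rest: an after potential
lasting tens of milliseconds follows, shaping excitability during repetitive
firing. Two mechanisms intertwine: voltage-gated K⁺ channels pull the early
phase toward E_K, and *capacitive discharge* — charge delivered through the
axon cable by the upstream spike — relaxes with the passive time constant of
the loaded cable and dominates the late phase. Separating them requires
simultaneous recordings from two sites of one thin axon plus spatially
restricted channel block, which is experimentally out of reach — but
straightforward in a biophysical model. `pearlchain` is that model, for
computational neuroscientists who want the complete simulation-and-analysis
pipeline as tested, scriptable R.

## The model

A mossy fiber is idealized as a "pearl chain": a soma (10 μm) followed by
ten thin axonal cylinders (0.2 μm × 100 μm) alternating with ten large *en
passant* boutons (4 μm), discretized at 1 segment/μm (1,050 segments),
sealed at both ends. Membrane currents follow Hodgkin–Huxley kinetics,

- I_Na = g_Na·m³h·(V − E_Na), 50 mS cm⁻² in axon/boutons, 10 in the soma,
  E_Na = +50 mV,
- I_K = g_K·n⁴·k_inact·(V − E_K), 36 mS cm⁻² everywhere, E_K = −85 mV,
  with a slow KV1.4-like inactivation gate applied multiplicatively,
- I_leak = (1/Rm)·(V − E_leak), with Cm = 1 μF cm⁻², Rm = 10⁴ Ω cm²,
  Ri = 110 Ω cm,

integrated implicitly (backward Euler or Crank–Nicolson, dt = 5 μs) on the
tridiagonal compartment system, with per-site recording of Vm and every
current component including I_cap = Cm·dV/dt. Gating kinetics are pluggable
through a registry; see the methods vignette
(`vignettes/mossy-fiber-afterpotential.Rmd`) for the shipped scheme and its
calibration.

The in-silico experiments are declarative protocols: distal conductance
knockouts that isolate the passively propagated spike, a steady-state
length-constant measurement, resting-potential sweeps with leak-reversal
retuning, ionic/capacitive component decomposition by subtraction, local
E_K overrides, current-step families, and membrane-capacitance sweeps. The
measurement layer provides exponential fits in space (length constant λ) and
time (relaxation constant τ), baseline alignment, and current-onset delays.

## Worked example

```r
library(pearlchain)

chain <- build_mossy_fiber_model()   # the default pearl-chain model
chain
#> <compartment_chain> 1050 segments, 21 sections, total length 1050 um
#>   sections: soma, axon1, bouton1, axon2, ...
#>   passive: Cm 1 uF/cm^2, Rm 10000 Ohm cm^2, Ri 110 Ohm cm, E_leak -81 mV
#>   gating scheme: hh_mf

## somatic stimulus; Na+/K+ conductances removed from the 8th axon onward
pp <- run_protocol(protocol_passive_propagation())

tr <- get_trace(pp$runs$control, "bouton7")
measure_ap_amplitude(tr$time, tr$value, baseline_window = c(0, 5))
#> AP amplitude at bouton 7: 120.7 mV

prof <- decay_profile(pp$runs$passive, pp$chain, from = "bouton7")
fit_spatial_decay(prof$distance, prof$amplitude)
#> <fit_result> spatial: amplitude 116.9711, decay constant 59.38872 um,
#>   offset 0, rms residual 1.623007 (n = 312)

amplitude_at_distance(pp$runs$passive, pp$chain, 100)
#> passive amplitude 100 um beyond the active region: 18.9 mV
```

The full spike (~121 mV at a mid-chain bouton) decays, once it must spread
passively, with a 1/e length of ~59 μm — far below the steady-state length
constant (~166 μm from `protocol_steady_state_lambda()`), because the cable
filters the fast spike transient much more strongly than a standing current.
~19 mV of passive depolarization still reaches the next bouton 100 μm away:
the capacitive contribution to the after potential there.

A command-line front end is installed at `inst/cli/pearlchain`
(`Rscript inst/cli/pearlchain fig1 --out out/` etc.) for running whole
protocols and writing trace CSVs plus fitted summaries.

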