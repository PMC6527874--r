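# Reference hippocampal mossy-fiber "pearl chain" model: a soma, ten thin
# axonal cylinders and ten large en passant boutons in strict alternation.
morphology:
  soma_diameter: 10       # um; represented as a cylinder with length = diameter
  n_boutons: 10
  axon:
    diameter: 0.2         # um
    length: 100.0         # um
  bouton_diameter: 4      # um; cylinder with length = diameter
passive:
  Cm: 1.0                 # uF/cm^2
  Rm: 10000.0             # Ohm cm^2
  Ri: 110.0               # Ohm cm
  E_leak: -81.0           # mV
channels:
  gating_scheme: hh_mf
  Na:
    density_axon: 50.0    # mS/cm^2 (axon and boutons)
    density_soma: 10.0    # mS/cm^2
    reversal: 50.0        # mV
  K:
    density: 36.0         # mS/cm^2, uniform
    reversal: -85.0       # mV
discretization:
  segments_per_um: 1
simulation:
  dt: 0.005               # ms (5 us)
  resting_potential: -80  # mV
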