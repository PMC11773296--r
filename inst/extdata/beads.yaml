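# Example depwave run configuration: polystyrene-like beads in a
# low-conductivity aqueous medium. SI units throughout.
system:
  eps_r_particle: 2.55
  sigma_particle: 1.0e-16     # S/m (bulk; surface conduction dominates)
  eps_r_medium: 78.5
  sigma_medium: 1.0e-4        # S/m
  radius: 1.25e-6             # m
  surface_conductance: 1.0e-9 # S
waveform:
  shape: rectangular
  v0: 72.5                    # V peak (145 Vpp)
  f0: 1.5e+4                  # Hz
  max_order: 199
analysis:
  field_gradient: 1.0e+12     # V^2/m^3, scalar standing in for grad|E_rms|^2
  comparison: peak            # equal peak amplitude (bench convention)
  tail: plateau
seed: 1
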