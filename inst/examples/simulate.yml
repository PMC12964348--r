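# Synthetic rigid-nanofiber curve on a pinhole-SANS grid.
model: flexible_cylinder_powerlaw
params:
  alpha1: 5
  radius: 16
  kuhn: 318
  contour: 5000
  alpha2: 1.0e-9
  decay: 4
  background: 0.01
instrument: d11
noise:
  relative_sigma: 0.02
seed: 1
output: sim_out
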