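mode: synthetic
seed: 1
design:
  shell_radii: [8.0, 12.0]
  link_threshold: 6.0
  gap_open: 11.0
  gap_extend: 1.0
  offset: 0
kinetics:
  noise_sd: 0.01
  n_conc: 8
  temperatures_C: [25.0, 40.0, 70.0]
  enzyme_conc: 1.0e-08
thermo:
  convention: association
  T_ref_C: 25.0
melt:
  noise_sd: 0.01
  grid_from: 40.0
  grid_to: 100.0
  grid_by: 0.5
tradeoff:
  n_wildtype: 6
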