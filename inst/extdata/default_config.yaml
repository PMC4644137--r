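compound:
  molecular_weight: 975.87
  dose_per_kg: 30.0
  cl_ref: 0.5
  vss_per_kg: 0.148
  v1_per_kg: 0.0545
  t_half_dist: 0.48
  t_half_elim: 16.3
  kd_albumin: 85.0
  fu_override: ~
  pka_acid: 0.78
  pka_base: 9.67
  logp: -1.2
  psa: 268.96
cohorts: []
design:
  n_trials: 10.0
  n_subjects: 10.0
  prop_female: 0.5
  dose_per_kg: 30.0
  horizon: 72.0
  global_seed: 2.0140612e+07
output:
  write_profiles: yes
  write_plots: yes
  plot_format: png
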