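# Desk-scale demo run: 10-region simulated cohort, fixed seed.
seed: 42
cohort:
  n_per_group: 2
  duration_s: 12
  effects:
    fov_cpl_slope: 0
bands: [Delta, Alpha, Beta1]
threshold: 0.30
responder_timepoint: post
anova_response: alpha_occ_strength
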