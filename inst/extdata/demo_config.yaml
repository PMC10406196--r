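# Demonstration analysis: simulated two-condition experiment, correlation
# tracking of the cond1 template against the cond2 baseline, group
# inference by exact Wilcoxon signed-rank and sign-flip permutation.
seed: 11
out_dir: ctt_demo_out
simulate:
  n_subjects: 8
  n_units: 80
  n_conditions: 2
  n_localizer_trials_per_condition: 16
  n_main_trials_per_condition: 16
  n_runs_localizer: 4
  n_chunks_main: 4
  noise_sd: 0.8
extract:
  normalize: none
track:
  metric: pearson
  target: cond1
  baseline: cond2
infer:
  n_perm: 1000
  alternative: greater
diagnostics: true
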