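{
  "config_hash": "405144a0",
  "seed": 21,
  "config": {
    "seed": 21,
    "out_dir": "ctt_out",
    "simulate": {
      "n_subjects": 5,
      "n_units": 40,
      "n_conditions": 2,
      "n_localizer_trials_per_condition": 16,
      "n_main_trials_per_condition": 16,
      "n_runs_localizer": 4,
      "n_chunks_main": 4,
      "noise_sd": 0.8
    },
    "extract": {
      "supertrial_k": 2,
      "normalize": "univariate",
      "smooth_window": {},
      "pca_fraction": 0.99
    },
    "track": {
      "metric": "pearson",
      "target": "cond1",
      "baseline": "cond2"
    },
    "infer": {
      "n_perm": 1000,
      "alternative": "greater"
    },
    "diagnostics": false
  },
  "artifacts": [
    {
      "name": "subject_indexes",
      "file": "subject_indexes.tsv",
      "kind": "table"
    },
    {
      "name": "group_tests",
      "file": "group_tests.tsv",
      "kind": "table"
    }
  ]
}
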