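# Default run configuration. Paths are resolved relative to the working
# directory; every seed below is derived from `seed` unless set explicitly.
seed: 1
threshold: 0.1
modalities: [eeg, mri, scale]
cohort:                 # synthetic-cohort generator (ignored when
  n_subjects: 82        # cohort_table/eeg_dir point at real data)
preprocess:
  lowcut: 0.5
  highcut: 100
  reject_sd: 7
spectral:
  n_segments: 20
  segment_length: 2000
complexity:
  l: 2
  n_bins: 16
microstates:
  window_ms: 100
  k: 7
regressor:
  n_trees: 100
  min_leaf: 5
  top_k: 500
  n_folds: 7
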