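# Example pipeline configuration: a small two-ROI cohort that runs in a
# few seconds.  Omitted fields fall back to the study-analog defaults.
sim:
  n_subjects_per_session: 4
  n_shared_subjects: 2
  n_voxels: 40
  rois: [V1, PFC]
  n_attention_runs: 4
  trials_per_attention_run: 20
  n_perception_runs: 2
  trials_per_perception_run: 20
effect:
  lambda: {V1: 0.6}
  g: 0.3
analysis:
  shrinkage: 0.1
  n_perm: 200
  alpha: 0.05
  q: 0.25
seed: 42
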