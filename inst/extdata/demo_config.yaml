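# Demo pipeline configuration for run_pipeline(): small problem sizes so a
# complete run (all stages) finishes in a few minutes on one CPU.
seed: 1
stages:
  synth: true
  preprocess: true
  ersp: true
  clusterstats: true
  association: true
  coherence: true
  specgc: true
  dcm: true
synth:
  n_trials_per_condition: 30
  fs: 500
  n_contacts: 8
  effect_band: [13.0, 30.0]
  effect_window: [1.0, 2.0]
  effect_gain_db: 3
preprocess:
  z_thresh: 6
  max_width_s: 0.25
ersp:
  freq_range: [4.0, 45.0]
  window_s: 0.512
  time_step: 0.02
  freq_step: 1
clusterstats:
  n_perm: 500
  alpha_sample: 0.01
  min_size: 30
association:
  n_patients: 40
  band: [13.0, 30.0]
coherence:
  freq_range: [4.0, 45.0]
  time_step: 0.02
  freq_step: 1
specgc:
  m_max: 12
  n_perm: 200
  level: 0.999
dcm:
  band: [2.0, 45.0]
  freq_step: 1
  n_subjects: 4
  generator_id: 2
  max_iter: 32
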