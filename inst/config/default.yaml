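# Default pipeline configuration. Every key shown here equals the
# package default; omit any key to get the same value.
seed: 1
out_dir: hopfec_out
log_level: info
acquisition:
  TR: 0.8
  n_samples: 696
activation_band:
  low: 0.05
  high: 0.15
  order: 2
fc_band:
  low: 0.008
  high: 0.08
  order: 2
gec:
  tau_seconds: 2.0
  epsilon: 0.02
  max_iter: 200
  patience: 30
  clip_max: 0.2
  sim_length_samples: 2784
  reverse_for_fmri: true
  hemisphere: L
cohort:
  n_participants: 23
  density: 0.3
  strength_scale: 0.1
  base_amplitude: 0.05
  subject_gain_jitter_sd: 0.1
  subject_coupling_jitter_sd: 0.1
battery:
  alpha: 0.02
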