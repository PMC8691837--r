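# Example end-to-end run configuration: a size-matched, texture-differing
# two-class mixture with one stained class, default optics and acquisition.
population:
  n_events: 2000
  seed: 101
  pitch: 0.5
  shape: [64, 32]
  classes:
    - name: smooth
      fraction: 0.5
      params: {diameter: 11, diameter_sd: 0.8, granularity: 0.2,
               granularity_sd: 0.05, nucleus_fraction: 0.4}
      stain: {green: 0}
    - name: granular
      fraction: 0.5
      params: {diameter: 11, diameter_sd: 0.8, granularity: 1.0,
               granularity_sd: 0.1, nucleus_fraction: 0.4}
      stain: {green: 30}
optics:
  modalities: [dGMI, ssGMI, bsGMI, fsGMI, bfGMI]
  pattern_flow: 128
  fill_fraction: 0.5
  pattern_seed: 20
  noise: {shot_scale: 10, read_sigma: 0.5}
acquisition:
  highpass_alpha: 0.995
  trigger_threshold: 3
  trigger_min_run: 3
  segment_length: 128
  pre_trigger: 8
  width_fraction: 0.5
gating:
  label: {channel: green, threshold: 1000,
          positive: granular, negative: smooth}
classifier:
  kernel: rbf
  C_grid: [1, 10, 100]
  gamma_grid: [0.001, 0.01, 0.1]
  inner_folds: 5
  modality_set: [dGMI, ssGMI]
  n_trials: 10
  n_train_per_class: 300
  n_test_per_class: 300
seed: 101
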