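# Default pipeline configuration: the study's session structure and the
# package's default simulation/analysis parameters. Any key can be
# omitted; omitted keys take these values.
design:
  n_blocks: 9
  trials_per_block: 18
  ready_lead: [2.6, 3.0]
  stim_duration: [3.4, 3.8]
  inter_trial: 3.0
  inter_block: 150.0
  fs: 1000
ground_truth:
  roi_erd:
    low:    {alpha: -8.0,  beta: -5.0}
    medium: {alpha: -12.0, beta: -8.0}
    high:   {alpha: -35.0, beta: -25.0}
  background_sd: 10.0
  background_exponent: 1.0
  alpha_rms: 10.0
  beta_rms: 6.0
  occipital_alpha_rms: 8.0
artifacts:
  pulse_rate: 35.0
  pulse_width_us: 300.0
  transient_amplitude: {low: 200.0, medium: 400.0, high: 800.0}
  bad_channels: []
  powerline_amplitude: 20.0
  baseline_powerline: 1.0
rejection:
  band: [48.0, 52.0]
  hp_cutoff: 0.1
  hp_order: 4
  welch_window: 1.0
  welch_overlap: 0.5
  sd_multiplier: 4.0
median_filter:
  window_ms: 10.0
  edge_policy: shrink
tfr:
  n_cycles: 7.0
  baseline: [-2.5, -1.5]
  stim_interval: [0.5, 2.5]
  nostim_interval: [-3.0, -1.0]
dose:
  alpha: 0.05
seed: 1
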