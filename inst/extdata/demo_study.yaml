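# Demo study configuration for mstate-ri / run_pipeline().
# Any field omitted here keeps the package default (see ?pipeline_config).

seed: 1

simulate:
  n_per_group: 6          # subjects per group (TMNMT, Placebo)
  n_channels: 19          # classic 10-20 montage; up to 60 (10-10 grid)
  fs_hz: 256              # simulated sampling rate
  length_s: 12            # per-recording duration, seconds
  n_states: 4             # microstate classes A-D
  mean_durations_ms: [60, 80, 100, 120]
  gfp_scale_uv: 9         # envelope scale; with noise 2 uV -> SNR ~ 4
  noise_sd_uv: 2
  oscillations:           # band-limited rhythms (amplitude in uV)
    alpha2: {low_hz: 10, high_hz: 13, amplitude_uv: 3}
    theta:  {low_hz: 4.5, high_hz: 7.5, amplitude_uv: 2}
  # example effect injection: shorten microstate B and damp alpha2 after
  # treatment in the TMNMT group
  effect_spec:
    TMNMT:
      post:
        duration_mult: {B: 0.8}
        band_db: {alpha2: -3}
  subject_sigma: {duration: 0.08, band_db: 1}

preprocess:
  band: [0.5, 100]        # broadband FIR band-pass, Hz
  notch_hz: [50, 100]
  epoch_length_s: 2
  threshold_uv: 100       # +/- amplitude rejection
  microstate_band: [2, 20]

welch:
  segment_s: 2
  overlap: 0.5
  window: hamming

microstate:
  k: 4
  min_separation_ms: 10   # GFP-peak pruning
  max_maps_per_recording: 120
  backfit_level: group    # or "grand"

stats:
  alpha: 0.05
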