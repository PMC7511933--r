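# Run configuration for the analysis scripts.
# Phantom and acquisition defaults mirror the simulated study conditions;
# the 16 x 16 phantom keeps a full six-dataset study quick to regenerate.
seed: 42
phantom:
  height: 16
  width: 16
  pixel_size: 100
acquisition:
  mz_min: 400
  mz_max: 2200
  raster_width: 100
preprocess:
  baseline_width: 20
  smoothing: medium
  interval_half_width: 0.156
  interval_statistic: mean
analysis:
  min_mass: 600
  min_separation: 0.312
  tolerance: 0.05
  floor: 5
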