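# Example cpoct run configuration.
# Omitted keys take their defaults (see defaultRunConfig()).
seed: 1
out_dir: cpoct-run
phantom:
  depthMm: 4.0
  deltaZMm: 0.005
  lateralPx: [128, 128]
  pitchXYMm: 0.009375
  surfaceDepthMm: 0.25
  muSampling: patch
estimator:
  tail_mode: truncate
  discretization: true
window: [0.105, 0.630]
roi_source: fixture
render_channels: [co, cross]
n_boot: 2000
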