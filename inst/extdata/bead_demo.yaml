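# Demo run: 5 um PAA bead in water, 64 x 64 px, reduced frame count.
scene:
  type: bead
  diameter: 5.0
  material: PAA
  medium: water
  grid: [64, 64]
  pixel_pitch: 0.1
optics:
  wavelength: 0.532
  mean_intensity: 1800.0
  visibility: 0.9
  snr_db: .inf
  full_scale: 4095
drive:
  frequency: 1000.0
  pressure_amplitude: 150.0
  power: 0.05
plan:
  n_steps: 20
  step_phase: 0.3141592653589793
  frames_per_step: 8
model:
  poisson_ratio: 0.5
  lateral_coupling: 0.0
seed: 1
denoise_sigma: 0.0
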