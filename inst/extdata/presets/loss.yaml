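# Phantom setting with scripted balloon-loss events: the balloon is
# teleported 30 mm through-plane at dynamic 40 and returned at dynamic 70,
# forcing two miss-revert-recalibrate cycles per session.
seed: 1
phantom:
  shape: [64, 64, 64]
  spacing_mm: 5
  tissue_level: 100
  body_margin_mm: 4
  texture_sd: 0.02
  vessels:
    - {type: tube, from: [40, -150, 20], to: [40, 150, 20], radius_mm: 15, intensity: 105}
    - {type: sphere, center: [-50, 0, -40], radius_mm: 25, intensity: 80}
trajectory:
  waypoints: [[0, -15, 0], [0, 15, 0], [0, -15, 0], [0, 15, 0],
              [0, -15, 0], [0, 15, 0], [0, -15, 0], [0, 15, 0],
              [0, -15, 0], [0, 15, 0], [0, -15, 0], [0, 15, 0]]
  step_mm: 3
  n_dynamics: 100
  jitter_sd_mm: 0.3
  radius_mm: 4
  brightness: 300
  loss: {at: 40, duration: 30, offset_mm: [0, 30, 0]}
acquisition:
  calibration_n_slices: 9
  runtime_n_slices: 3
  thickness_mm: 10
  fov_mm: [300, 300]
  matrix: [128, 128]
  normal: [0, 1, 0]
  calibration_prep_deg: 90
  runtime_prep_deg: 50
  noise_sd: 2
detector:
  backend: CLASSICAL
  z_threshold: 5
  min_area_px: 3
  max_area_px: 400
tracker:
  miss_threshold: 5
  latency_dynamics: 1
  selection_statistic: mean
evaluation:
  cnr_annulus_px: [5, 10]
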