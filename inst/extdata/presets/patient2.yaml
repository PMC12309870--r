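# Pediatric setting 2: coronal Calibration (12 slices) / sagittal Runtime,
# 10 mm slices, FOV 400 x 280 mm, matrix 160, 117 dynamics.
seed: 1
phantom:
  shape: [64, 64, 64]
  spacing_mm: 5
  tissue_level: 100
  body_margin_mm: 4
  texture_sd: 0.02
  vessels:
    - {type: tube, from: [40, -150, 20], to: [40, 150, 20], radius_mm: 12, intensity: 105}
trajectory:
  waypoints: [[-25, 0, 0], [25, 0, 0], [-25, 0, 0], [25, 0, 0],
              [-25, 0, 0], [25, 0, 0], [-25, 0, 0], [25, 0, 0],
              [-25, 0, 0], [25, 0, 0], [-25, 0, 0]]
  step_mm: 4
  n_dynamics: 117
  jitter_sd_mm: 0.3
  radius_mm: 4
  brightness: 300
acquisition:
  calibration_n_slices: 12
  runtime_n_slices: 3
  thickness_mm: 10
  fov_mm: [400, 280]
  matrix: [160, 160]
  calibration_normal: [0, 1, 0]
  runtime_normal: [1, 0, 0]
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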