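# Experiment orchestration: YAML configs, named presets, end-to-end runs.

config_schema <- list(
  seed = NULL,
  phantom = c("shape", "spacing_mm", "tissue_level", "body_margin_mm",
              "texture_sd", "vessels"),
  trajectory = c("waypoints", "step_mm", "n_dynamics", "jitter_sd_mm",
                 "radius_mm", "brightness", "loss"),
  acquisition = c("calibration_n_slices", "runtime_n_slices", "thickness_mm",
                  "fov_mm", "matrix", "normal", "calibration_normal",
                  "runtime_normal", "calibration_center_mm",
                  "calibration_prep_deg", "runtime_prep_deg", "noise_sd"),
  detector = c("backend", "z_threshold", "min_area_px", "max_area_px",
               "model_path", "prob_threshold"),
  tracker = c("miss_threshold", "latency_dynamics", "selection_statistic"),
  evaluation = c("cnr_annulus_px")
)

#' Load and validate an experiment configuration
#'
#' Reads a YAML experiment description (or takes an equivalent named
#' list). All six blocks — `phantom`, `trajectory`, `acquisition`,
#' `detector`, `tracker`, `evaluation` — plus a `seed` must be present;
#' unknown blocks or keys are rejected with the offending name. Structural
#' constraints (odd Runtime slice count, positive thickness) are enforced
#' here so a bad config fails before anything is written.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The validated config (named list) with class
#'   `experiment_config`.
#' @export
load_experiment_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML mapping or a named list.")
  unknown_blocks <- setdiff(names(config), names(config_schema))
  if (length(unknown_blocks)) {
    abort(sprintf("unknown config block(s): %s",
                  paste(unknown_blocks, collapse = ", ")))
  }
  missing <- setdiff(names(config_schema), names(config))
  if (length(missing)) {
    abort(sprintf("missing config block(s): %s", paste(missing, collapse = ", ")))
  }
  for (blk in setdiff(names(config_schema), "seed")) {
    bad <- setdiff(names(config[[blk]]), config_schema[[blk]])
    if (length(bad)) {
      abort(sprintf("unknown key(s) in block '%s': %s", blk,
                    paste(bad, collapse = ", ")))
    }
  }
  acq <- config$acquisition
  if ((acq$runtime_n_slices %||% 3L) %% 2L == 0L) {
    abort("acquisition$runtime_n_slices must be odd.")
  }
  if ((acq$thickness_mm %||% 10) <= 0) {
    abort("acquisition$thickness_mm must be > 0.")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    abort("`seed` must be a single integer.")
  }
  structure(config, class = c("experiment_config", "list"))
}

#' Named experiment presets
#'
#' Ready-made configurations shipped with the package: `"phantom"`
#' (9-slice coronal Calibration / 3-slice Runtime stacks, 10 mm slices,
#' FOV 300 mm, matrix 128, 100 dynamics), `"patient1"` (7 mm, matrix 112,
#' 59 dynamics), `"patient2"` (10 mm, matrix 160, FOV 400 x 280, 12
#' Calibration slices, 117 dynamics), `"patient3"` (6 mm, matrix 160, 78
#' dynamics), and `"loss"` (the phantom setting with one scripted
#' balloon-loss event).
#'
#' @param name Preset name.
#' @return A validated `experiment_config`.
#' @export
preset_config <- function(name = c("phantom", "patient1", "patient2",
                                   "patient3", "loss")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "cathtrack", mustWork = TRUE)
  load_experiment_config(path)
}

# --- builders from config blocks ------------------------------------------

build_phantom_from_config <- function(cfg) {
  ph <- cfg$phantom
  build_phantom(
    shape = unlist(ph$shape %||% c(64L, 64L, 64L)),
    vessel_spec = ph$vessels %||% list(),
    tissue_level = ph$tissue_level %||% 100,
    spacing_mm = unlist(ph$spacing_mm %||% 2),
    body_margin_mm = ph$body_margin_mm %||% 4,
    texture_sd = ph$texture_sd %||% 0,
    seed = cfg$seed)
}

build_trajectory_from_config <- function(cfg, seed = cfg$seed) {
  tr <- cfg$trajectory
  wp <- lapply(tr$waypoints, unlist)
  args <- list(waypoints = wp, step_mm = tr$step_mm %||% 4,
               n_dynamics = tr$n_dynamics %||% 100,
               jitter_sd_mm = tr$jitter_sd_mm %||% 0,
               seed = seed, radius_mm = tr$radius_mm %||% 4,
               brightness = tr$brightness %||% 300)
  if (!is.null(tr$loss)) {
    do.call(trajectory_with_loss, c(args, list(
      loss_at = tr$loss$at, loss_duration = tr$loss$duration,
      offset_mm = unlist(tr$loss$offset_mm))))
  } else {
    do.call(simulate_trajectory, args)
  }
}

build_prescriptions_from_config <- function(cfg) {
  acq <- cfg$acquisition
  base_normal <- unlist(acq$normal %||% c(0, 1, 0))
  cal_normal <- unit3(unlist(acq$calibration_normal %||% base_normal))
  run_normal <- unit3(unlist(acq$runtime_normal %||% base_normal))
  center <- as_point3(unlist(acq$calibration_center_mm %||% c(0, 0, 0)))
  fov <- unlist(acq$fov_mm %||% c(300, 300))
  mat <- unlist(acq$matrix %||% c(128, 128))
  thick <- acq$thickness_mm %||% 10
  list(
    calibration = slice_prescription(center, cal_normal,
                                     acq$calibration_n_slices %||% 9L,
                                     thick, fov, mat),
    runtime = slice_prescription(center, run_normal,
                                 acq$runtime_n_slices %||% 3L,
                                 thick, fov, mat))
}

build_detector_from_config <- function(cfg) {
  det <- cfg$detector
  backend <- toupper(det$backend %||% "CLASSICAL")
  model <- NULL
  if (backend == "UNET") {
    if (is.null(det$model_path)) {
      abort("detector backend UNET requires `model_path` (train one with the `train` subcommand or train_unet()).")
    }
    model <- load_detector_model(det$model_path)
  }
  detector_config(backend = backend,
                  z_threshold = det$z_threshold %||% 5,
                  min_area_px = det$min_area_px %||% 3L,
                  max_area_px = det$max_area_px %||% 400L,
                  model = model,
                  prob_threshold = det$prob_threshold %||% 0.5)
}

build_tracker_from_config <- function(cfg) {
  pres <- build_prescriptions_from_config(cfg)
  trk <- cfg$tracker
  tracker_config(pres$calibration, pres$runtime,
                 miss_threshold = trk$miss_threshold %||% 5L,
                 latency_dynamics = trk$latency_dynamics %||% 1L,
                 selection_statistic = trk$selection_statistic %||% "mean")
}

#' Run a complete experiment from a configuration
#'
#' Builds the phantom, trajectory, detector and tracker from the config,
#' runs the closed-loop session, and writes a reproducible artifact tree:
#' `phantom.nii.gz`, `session.csv` (one row per dynamic),
#' `session_summary.json`, `scores.csv` (per mode and level),
#' `cnr.csv`, the resolved `config.yaml`, and `manifest.json` (file list,
#' config MD5, seed). Re-running with the same config and seed reproduces
#' the CSV content byte for byte.
#'
#' @param config Path to a YAML config, a named list, or an
#'   `experiment_config`.
#' @param out_dir Output directory (created; must be empty or absent
#'   unless `overwrite`).
#' @param seed Optional override of the config seed.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The `cathtrack_session`, invisibly, with the artifact paths in
#'   attribute `"artifacts"`.
#' @export
run_experiment <- function(config, out_dir, seed = NULL, overwrite = FALSE) {
  cfg <- load_experiment_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    abort(sprintf("output directory '%s' is not empty.", out_dir))
  }

  volume <- build_phantom_from_config(cfg)
  traj <- build_trajectory_from_config(cfg)
  detector <- build_detector_from_config(cfg)
  tracker <- build_tracker_from_config(cfg)
  ev <- cfg$evaluation
  session <- run_session(
    volume, traj, detector, tracker,
    noise_sd = cfg$acquisition$noise_sd %||% 2,
    seed = cfg$seed,
    calibration_prep_deg = cfg$acquisition$calibration_prep_deg %||% 90,
    runtime_prep_deg = cfg$acquisition$runtime_prep_deg %||% 50,
    compute_cnr = TRUE,
    cnr_annulus_px = unlist(ev$cnr_annulus_px %||% c(5, 10)))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    phantom = file.path(out_dir, "phantom.nii.gz"),
    session = file.path(out_dir, "session.csv"),
    summary = file.path(out_dir, "session_summary.json"),
    scores = file.path(out_dir, "scores.csv"),
    cnr = file.path(out_dir, "cnr.csv"),
    config = file.path(out_dir, "config.yaml"),
    manifest = file.path(out_dir, "manifest.json"))

  write_volume_nifti(volume, paths$phantom)
  write.csv(session$log, paths$session, row.names = FALSE)
  jsonlite::write_json(as.list(session_statistics(session)), paths$summary,
                       auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(session_scores(session), paths$scores, row.names = FALSE)
  cnr_tbl <- dplyr::select(
    dplyr::filter(session$log, !is.na(.data$cnr)),
    "dynamic", "mode", label = "stack_label", "cnr", "rel_contrast_pct")
  write.csv(cnr_tbl, paths$cnr, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), paths$config)
  jsonlite::write_json(
    list(seed = cfg$seed,
         config_md5 = unname(tools::md5sum(paths$config)),
         files = vapply(paths, basename, character(1))),
    paths$manifest, auto_unbox = TRUE)

  attr(session, "artifacts") <- paths
  invisible(session)
}
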