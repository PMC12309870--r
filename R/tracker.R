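#' Select the stack-level balloon region
#'
#' Stack-based segmentation: among every candidate region of every slice of
#' a stack, the single region with the highest signal intensity is
#' selected; the others (balloon appearances in adjacent slices, spurious
#' detections) are discarded. Ties are broken by larger area, then lower
#' slice index. The balloon's 3D world position follows from the selected
#' region's centre of mass via [region_to_3d()].
#'
#' @param segmentations A list of `slice_segmentation` tibbles (one per
#'   slice, from [segment_slice()]) or a single row-bound tibble.
#' @param prescription The stack's [slice_prescription()] (needed for 3D
#'   localization; may be `NULL` to skip it).
#' @param statistic Region intensity statistic to maximise:
#'   `"mean"` (default) or `"peak"`.
#' @return An object of class `stack_detection`: list with `found`, and —
#'   when found — `region` (one-row tibble), `slice_index` (0-based) and
#'   `position_mm`.
#' @export
select_stack_region <- function(segmentations, prescription = NULL,
                                statistic = c("mean", "peak")) {
  statistic <- match.arg(statistic)
  regs <- if (is.data.frame(segmentations)) segmentations else
    dplyr::bind_rows(segmentations)
  if (!nrow(regs)) {
    return(structure(list(found = FALSE, region = NULL,
                          slice_index = NULL, position_mm = NULL),
                     class = "stack_detection"))
  }
  key <- if (statistic == "mean") regs$mean_intensity else regs$peak_intensity
  ord <- order(-key, -regs$area_px, regs$slice_index)
  best <- regs[ord[1L], ]
  pos <- if (is.null(prescription)) NULL else
    region_to_3d(best, prescription, best$slice_index)
  structure(list(found = TRUE, region = best,
                 slice_index = best$slice_index, position_mm = pos),
            class = "stack_detection")
}

#' Map a region's centre of mass to a 3D world position
#'
#' The in-plane offset from the image centre is scaled by the pixel pitch
#' (`fov_mm / matrix`); the through-plane coordinate is the centre of the
#' slice the region was found in.
#'
#' @param region One-row `slice_segmentation` tibble (needs `com_row`,
#'   `com_col`).
#' @param prescription The stack's [slice_prescription()].
#' @param slice_index 0-based slice the region belongs to.
#' @return World coordinate (mm), length 3.
#' @export
region_to_3d <- function(region, prescription, slice_index) {
  nu <- prescription$matrix[1]; nv <- prescription$matrix[2]
  off_u <- (region$com_col - 1 - (nu - 1) / 2) * prescription$fov_mm[1] / nu
  off_v <- (region$com_row - 1 - (nv - 1) / 2) * prescription$fov_mm[2] / nv
  slice_centers(prescription)[slice_index + 1L, ] +
    off_u * prescription$in_plane_axes[, 1] +
    off_v * prescription$in_plane_axes[, 2]
}

#' Classify a Runtime stack outcome
#'
#' The three possible outcomes of a Runtime acquisition: the catheter is
#' identified in the central slice (`CENTRAL`), in one of the outer slices
#' (`OUTER`, with a through-plane direction sign), or not identified
#' (`NONE`).
#'
#' @param detection A `stack_detection`.
#' @param n_slices Slice count of the stack; must be odd so the central
#'   slice is well defined.
#' @return List with `case` (`"CENTRAL"`, `"OUTER"` or `"NONE"`) and
#'   `outer_direction` (`-1`/`+1`, present only for `OUTER`).
#' @export
classify_outcome <- function(detection, n_slices = 3L) {
  if (n_slices %% 2L == 0L) abort("`n_slices` must be odd for a central slice to exist.")
  if (!detection$found) return(list(case = "NONE", outer_direction = NULL))
  central <- (n_slices - 1L) %/% 2L
  if (detection$slice_index == central) {
    list(case = "CENTRAL", outer_direction = NULL)
  } else {
    list(case = "OUTER",
         outer_direction = sign(detection$slice_index - central))
  }
}

#' Tracker configuration
#'
#' Bundles the Calibration and Runtime stack templates with the control
#' parameters of the prospective state machine: the consecutive-miss
#' threshold that triggers the revert to Calibration mode (default 5) and
#' the feedback latency in dynamics (default 1: the prescription computed
#' from stack `d` governs acquisition `d + 1`).
#'
#' @param calibration A [slice_prescription()] for Calibration stacks (the
#'   fixed stack covering the anticipated catheter trajectory).
#' @param runtime A [slice_prescription()] template for Runtime stacks;
#'   `n_slices` must be odd (3 in routine use). Its centre is replaced by
#'   the tracked balloon position.
#' @param miss_threshold Consecutive Runtime misses before reverting to
#'   Calibration mode.
#' @param latency_dynamics Feedback latency (>= 1), in dynamics.
#' @param selection_statistic Passed to [select_stack_region()].
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(calibration, runtime, miss_threshold = 5L,
                           latency_dynamics = 1L,
                           selection_statistic = "mean") {
  stopifnot(inherits(calibration, "slice_prescription"),
            inherits(runtime, "slice_prescription"))
  if (runtime$n_slices %% 2L == 0L) {
    abort("Runtime stacks must have an odd slice count.")
  }
  if (miss_threshold < 1L) abort("`miss_threshold` must be >= 1.")
  if (latency_dynamics < 1L) abort("`latency_dynamics` must be >= 1.")
  structure(list(calibration = calibration, runtime = runtime,
                 miss_threshold = as.integer(miss_threshold),
                 latency_dynamics = as.integer(latency_dynamics),
                 selection_statistic = selection_statistic),
            class = "tracker_config")
}

#' Initial tracker state
#'
#' The tracker starts in Calibration mode with an empty miss counter and a
#' pending-prescription queue of length `latency_dynamics` filled with the
#' Calibration template, so the first acquisitions are Calibration stacks.
#'
#' @param config A [tracker_config()].
#' @return An object of class `tracker_state`.
#' @export
new_tracker_state <- function(config) {
  entry <- list(prescription = config$calibration, mode = "CALIBRATION")
  structure(list(mode = "CALIBRATION", miss_count = 0L,
                 runtime_center_mm = NULL,
                 pending = rep(list(entry), config$latency_dynamics),
                 config = config),
            class = "tracker_state")
}

#' Advance the tracking state machine by one dynamic
#'
#' Applies the prospective control rules to the detection obtained from the
#' stack just acquired:
#'
#' * Calibration stack, balloon found: switch to Runtime mode, centring the
#'   Runtime template on the detected 3D position; reset the miss counter.
#' * Calibration stack, not found: repeat Calibration.
#' * Runtime `CENTRAL` (Case 1): keep the current centre; reset misses.
#' * Runtime `OUTER` (Case 2): shift the Runtime centre by exactly one
#'   slice thickness along the stack normal, toward the slice containing
#'   the catheter; reset misses.
#' * Runtime `NONE` (Case 3): keep the centre; increment the miss counter;
#'   once `miss_threshold` consecutive misses accumulate, revert to
#'   Calibration mode and clear the counter.
#'
#' The emitted prescription enters the latency queue; the prescription used
#' for the next acquisition is the one leaving the queue.
#'
#' @param state A `tracker_state`.
#' @param outcome Output of [classify_outcome()] (Runtime stacks; ignored
#'   for Calibration stacks).
#' @param detection The stack's `stack_detection`.
#' @param stack_mode Mode of the stack that was actually acquired
#'   (`"CALIBRATION"`/`"RUNTIME"`); defaults to the state's mode, which is
#'   correct at latency 1.
#' @return List with `state` (updated), `emitted` (the queue entry just
#'   pushed: `prescription` + `mode`) and `next_entry` (the queue entry the
#'   next acquisition will use).
#' @export
advance_state <- function(state, outcome, detection,
                          stack_mode = state$mode) {
  stopifnot(inherits(state, "tracker_state"))
  cfg <- state$config
  switched_to_runtime <- FALSE
  switched_to_calibration <- FALSE

  if (stack_mode == "CALIBRATION") {
    if (detection$found) {
      state$mode <- "RUNTIME"
      state$runtime_center_mm <- detection$position_mm
      state$miss_count <- 0L
      switched_to_runtime <- TRUE
    } else {
      state$mode <- "CALIBRATION"
      state$miss_count <- 0L
    }
  } else {
    case <- outcome$case
    if (case == "CENTRAL") {
      state$miss_count <- 0L
    } else if (case == "OUTER") {
      state$runtime_center_mm <- state$runtime_center_mm +
        outcome$outer_direction * cfg$runtime$thickness_mm *
        cfg$runtime$normal
      state$miss_count <- 0L
    } else {
      state$miss_count <- state$miss_count + 1L
      if (state$miss_count >= cfg$miss_threshold) {
        state$mode <- "CALIBRATION"
        state$miss_count <- 0L
        switched_to_calibration <- TRUE
      }
    }
  }

  emitted <- if (state$mode == "CALIBRATION") {
    list(prescription = cfg$calibration, mode = "CALIBRATION")
  } else {
    list(prescription = recenter_prescription(cfg$runtime,
                                              state$runtime_center_mm),
         mode = "RUNTIME")
  }
  state$pending <- c(state$pending[-1L], list(emitted))
  state$switched_to_runtime <- switched_to_runtime
  state$switched_to_calibration <- switched_to_calibration
  list(state = state, emitted = emitted, next_entry = state$pending[[1L]])
}

#' Run a closed-loop tracking session
#'
#' Simulates the full prospective loop over all dynamics of a trajectory:
#' acquire the pending stack from the digital phantom, segment every slice
#' with the configured detector, select the stack-level region, classify
#' the outcome, advance the state machine, and log everything — including
#' the ground-truth balloon position, whether it truly lay within the
#' acquired slab, and slice-/stack-level detection labels against the
#' simulator's ground truth.
#'
#' @param volume A [voxel_volume()] phantom.
#' @param traj A [trajectory()]; its length sets the number of dynamics.
#' @param detector A [detector_config()].
#' @param tracker A [tracker_config()].
#' @param noise_sd Additive noise SD for every acquisition.
#' @param seed Experiment seed; the whole session is reproducible.
#' @param calibration_prep_deg,runtime_prep_deg Preparation pulse angles
#'   per mode (defaults 90 and 50 degrees).
#' @param compute_cnr Also compute the per-dynamic balloon/background CNR
#'   of the stack-truth slice (adds `cnr`, `rel_contrast_pct` columns).
#' @param cnr_annulus_px Background annulus for [compute_cnr()].
#' @param keep_stacks Retain the acquired `stack_images` objects in the
#'   result (memory-heavy; default `FALSE`).
#' @return An object of class `cathtrack_session`: `log` (one tibble row
#'   per dynamic), the configs, and (optionally) the raw stacks. Use
#'   [tidy()], [glance()], [session_statistics()], [autoplot()].
#' @export
run_session <- function(volume, traj, detector = detector_config(),
                        tracker, noise_sd = 2, seed = 1L,
                        calibration_prep_deg = 90, runtime_prep_deg = 50,
                        compute_cnr = FALSE, cnr_annulus_px = c(5, 10),
                        keep_stacks = FALSE) {
  stopifnot(inherits(tracker, "tracker_config"),
            inherits(traj, "catheter_trajectory"))
  n_dyn <- length(traj)
  state <- new_tracker_state(tracker)
  tissue_cache <- new.env(parent = emptyenv())
  rows <- vector("list", n_dyn)
  stacks <- if (keep_stacks) vector("list", n_dyn) else NULL

  for (d in seq_len(n_dyn) - 1L) {
    entry <- state$pending[[1L]]
    presc <- entry$prescription
    balloon <- balloon_at(traj, d)
    stack <- acquire_stack_cached(volume, balloon, presc, entry$mode,
                                  dynamic_index = d, noise_sd = noise_sd,
                                  seed = seed, cache = tissue_cache,
                                  prep_angle_deg = if (entry$mode == "CALIBRATION")
                                    calibration_prep_deg else runtime_prep_deg)
    if (keep_stacks) stacks[[d + 1L]] <- stack

    segs <- lapply(seq_len(presc$n_slices) - 1L, function(i) {
      segment_slice(stack$slices[[i + 1L]]$pixels, detector, slice_index = i)
    })
    det <- select_stack_region(segs, presc,
                               statistic = tracker$selection_statistic)
    outcome <- if (entry$mode == "RUNTIME") {
      classify_outcome(det, presc$n_slices)
    } else {
      list(case = NA_character_, outer_direction = NULL)
    }

    # --- evaluation against simulator ground truth
    masks <- lapply(seq_len(presc$n_slices) - 1L, function(i) {
      truth_slice_mask(balloon, presc, i)
    })
    slice_labels <- vapply(seq_along(segs), function(i) {
      label_slice(segs[[i]], masks[[i]], stack$slices[[i]]$pixels)
    }, character(1))
    st <- stack_truth(masks, lapply(stack$slices, `[[`, "pixels"))
    stack_label <- label_stack(det, st)
    cnr_rec <- if (compute_cnr && !is.na(st$slice_index)) {
      compute_cnr(stack$slices[[st$slice_index + 1L]]$pixels, st$mask,
                  annulus_px = cnr_annulus_px, label = stack_label)
    } else NULL

    adv <- advance_state(state, outcome, det, stack_mode = entry$mode)
    state <- adv$state
    outcome_case <- if (entry$mode == "RUNTIME") outcome$case else NA_character_
    shift_val <- if (identical(outcome$case, "OUTER")) {
      outcome$outer_direction * tracker$runtime$thickness_mm
    } else 0

    rows[[d + 1L]] <- tibble::tibble(
      dynamic = d,
      mode = entry$mode,
      prep_angle_deg = stack$prep_angle_deg,
      found = det$found,
      outcome = outcome_case,
      det_slice = if (det$found) det$slice_index else NA_integer_,
      det_x = if (det$found) det$position_mm[1] else NA_real_,
      det_y = if (det$found) det$position_mm[2] else NA_real_,
      det_z = if (det$found) det$position_mm[3] else NA_real_,
      truth_x = balloon$position_mm[1],
      truth_y = balloon$position_mm[2],
      truth_z = balloon$position_mm[3],
      truth_in_slab = point_in_slab(presc, balloon$position_mm),
      truth_offset_mm = through_plane_offset(presc, balloon$position_mm),
      stack_center_x = presc$center_mm[1],
      stack_center_y = presc$center_mm[2],
      stack_center_z = presc$center_mm[3],
      shift_mm = shift_val,
      miss_count = state$miss_count,
      switch_to_runtime = state$switched_to_runtime,
      switch_to_calibration = state$switched_to_calibration,
      stack_label = stack_label,
      cnr = if (is.null(cnr_rec)) NA_real_ else cnr_rec$cnr,
      rel_contrast_pct = if (is.null(cnr_rec)) NA_real_ else
        cnr_rec$rel_contrast_pct,
      slice_tp = sum(slice_labels == "TP"),
      slice_fp = sum(slice_labels == "FP"),
      slice_fn = sum(slice_labels == "FN"),
      slice_tn = sum(slice_labels == "TN")
    )
  }

  structure(list(log = dplyr::bind_rows(rows), detector = detector,
                 tracker = tracker, noise_sd = noise_sd, seed = seed,
                 stacks = stacks),
            class = "cathtrack_session")
}

# acquire_stack with a per-session memo of the (expensive, deterministic)
# slab-averaged tissue term, keyed on slice geometry. Runtime stacks revisit
# the same centres after shifts, so the cache pays off quickly.
acquire_stack_cached <- function(volume, balloon, prescription, mode,
                                 dynamic_index, noise_sd, seed, cache,
                                 prep_angle_deg = NULL) {
  prep <- if (!is.null(prep_angle_deg)) prep_angle_deg else
    if (mode == "CALIBRATION") 90 else 50
  ca <- cos(prep * pi / 180)
  if (abs(ca) < 1e-12) ca <- 0
  n <- prescription$n_slices
  slices <- vector("list", n)
  for (i in seq_len(n) - 1L) {
    if (ca != 0) {
      key <- paste(c(round(slice_centers(prescription)[i + 1L, ], 6),
                     round(prescription$normal, 6), prescription$matrix,
                     prescription$fov_mm, prescription$thickness_mm),
                   collapse = "|")
      tissue <- cache[[key]]
      if (is.null(tissue)) {
        tissue <- sample_slice(volume, NULL, prescription, i,
                               prep_angle_deg = 0, noise_sd = 0)$pixels
        cache[[key]] <- tissue
      }
      img <- ca * tissue
    } else {
      img <- matrix(0, prescription$matrix[2], prescription$matrix[1])
    }
    w <- partial_volume_weight(
      through_plane_offset(prescription, balloon$position_mm) -
        through_plane_offset(
          prescription, slice_centers(prescription)[i + 1L, ]),
      balloon$radius_mm, prescription$thickness_mm)
    if (w > 0) {
      s2 <- balloon_sigma_mm(balloon$radius_mm)^2
      img <- img + balloon$brightness * w *
        exp(-balloon_dist2(balloon, prescription, i) / (2 * s2))
    }
    if (noise_sd > 0) {
      img <- img + matrix(
        with_seed(substream_seed(seed, dynamic_index, i), {
          rnorm(length(img), 0, noise_sd)
        }), nrow(img), ncol(img))
    }
    img[img < 0] <- 0
    slices[[i + 1L]] <- structure(
      list(pixels = img, prescription = prescription, slice_index = i,
           prep_angle_deg = prep, noise_sd = noise_sd),
      class = "slice_image")
  }
  structure(list(slices = slices, mode = mode,
                 dynamic_index = as.integer(dynamic_index),
                 prescription = prescription, prep_angle_deg = prep),
            class = "stack_images")
}

#' @export
print.cathtrack_session <- function(x, ...) {
  st <- session_statistics(x)
  cat(sprintf("<cathtrack_session> %d dynamics, seed %d\n",
              nrow(x$log), x$seed))
  cat(sprintf("  Runtime/Calibration time: %.0f%%/%.0f%%; switches to Calibration: %d\n",
              100 * st$runtime_fraction, 100 * st$calibration_fraction,
              st$switch_count))
  invisible(x)
}
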