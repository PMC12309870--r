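#' Balloon ground truth
#'
#' The tracked object: a gadolinium-filled catheter-tip balloon, reduced to
#' a sphere with a world position, an effective radius and an unsaturated
#' signal level. The brightness is the balloon's intrinsic signal; the
#' short-T1 gadolinium filling means it is not attenuated by the saturation
#' preparation that suppresses tissue.
#'
#' @param position_mm World coordinate of the balloon centre (mm).
#' @param radius_mm Effective spherical radius (> 0), mm.
#' @param brightness Unsaturated balloon signal (> 0), arbitrary units.
#' @return An object of class `balloon_truth`.
#' @export
balloon_truth <- function(position_mm, radius_mm = 4, brightness = 300) {
  stopifnot_scalar_number(radius_mm, "radius_mm", 0, strict = TRUE)
  stopifnot_scalar_number(brightness, "brightness", 0, strict = TRUE)
  structure(list(position_mm = as_point3(position_mm, "position_mm"),
                 radius_mm = radius_mm, brightness = brightness),
            class = "balloon_truth")
}

#' Catheter trajectory over dynamics
#'
#' One balloon state per dynamic (dynamic counter origin 0). Constructed
#' directly from a positions matrix or via [simulate_trajectory()].
#'
#' @param positions_mm `n_dynamics` x 3 matrix of balloon centres (mm).
#' @param radius_mm,brightness Balloon geometry/signal, as [balloon_truth()].
#' @return An object of class `catheter_trajectory`.
#' @export
trajectory <- function(positions_mm, radius_mm = 4, brightness = 300) {
  positions_mm <- as.matrix(positions_mm)
  if (ncol(positions_mm) != 3L || nrow(positions_mm) < 1L ||
      any(!is.finite(positions_mm))) {
    abort("`positions_mm` must be a finite n x 3 matrix with n >= 1.")
  }
  structure(list(positions_mm = positions_mm, radius_mm = radius_mm,
                 brightness = brightness),
            class = "catheter_trajectory")
}

#' @export
length.catheter_trajectory <- function(x) nrow(x$positions_mm)

#' Balloon state at one dynamic
#'
#' @param traj A [trajectory()].
#' @param dynamic_index 0-based dynamic.
#' @return A [balloon_truth()].
#' @export
balloon_at <- function(traj, dynamic_index) {
  stopifnot(inherits(traj, "catheter_trajectory"))
  i <- as.integer(dynamic_index) + 1L
  if (i < 1L || i > nrow(traj$positions_mm)) abort("dynamic_index out of range.")
  balloon_truth(traj$positions_mm[i, ], traj$radius_mm, traj$brightness)
}

#' Simulate catheter navigation along waypoints
#'
#' Moves the balloon along a piecewise-linear path through `waypoints` at a
#' constant arc-length speed of `step_mm` per dynamic, clamped at the final
#' waypoint, with optional isotropic Gaussian positional jitter emulating
#' hand motion and physiology.
#'
#' @param waypoints List (or n x 3 matrix) of at least 2 world points (mm).
#' @param step_mm Displacement per dynamic along the path (>= 0), mm.
#' @param n_dynamics Number of dynamics (>= 1).
#' @param jitter_sd_mm SD of isotropic Gaussian jitter added per dynamic.
#' @param seed Integer seed (jitter only).
#' @param radius_mm,brightness Balloon parameters, see [balloon_truth()].
#' @return A [trajectory()] of length `n_dynamics`.
#' @examples
#' tr <- simulate_trajectory(list(c(0, 0, 0), c(0, 0, 100)),
#'                           step_mm = 10, n_dynamics = 5)
#' tr$positions_mm
#' @export
simulate_trajectory <- function(waypoints, step_mm, n_dynamics,
                                jitter_sd_mm = 0, seed = 1L,
                                radius_mm = 4, brightness = 300) {
  if (is.list(waypoints)) waypoints <- do.call(rbind, lapply(waypoints, as_point3))
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 2L) abort("need >= 2 waypoints.")
  stopifnot_scalar_number(step_mm, "step_mm", 0)
  if (n_dynamics < 1L) abort("`n_dynamics` must be >= 1.")

  seg <- diff(waypoints)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- pmin((seq_len(n_dynamics) - 1) * step_mm, total)
  pos <- t(vapply(s, function(si) {
    if (total == 0) return(waypoints[1L, ])
    k <- findInterval(si, cum, rightmost.closed = TRUE)
    k <- min(k, nrow(seg))
    f <- if (seg_len[k] > 0) (si - cum[k]) / seg_len[k] else 0
    waypoints[k, ] + f * seg[k, ]
  }, numeric(3)))
  if (jitter_sd_mm > 0) {
    jit <- with_seed(substream_seed(seed, 77L), {
      matrix(rnorm(3 * n_dynamics, 0, jitter_sd_mm), ncol = 3L)
    })
    pos <- pos + jit
  }
  trajectory(pos, radius_mm = radius_mm, brightness = brightness)
}

#' Trajectory with scripted balloon-loss events
#'
#' Builds a navigation trajectory and then teleports the balloon by
#' `offset_mm` for a contiguous window of dynamics, emulating abrupt loss of
#' the device from the Runtime stack (for example, a rapid pull-back): from
#' dynamic `loss_at` (0-based) to `loss_at + loss_duration - 1` the balloon
#' sits at its base position plus `offset_mm`, then returns to the base
#' path.
#'
#' @inheritParams simulate_trajectory
#' @param loss_at 0-based dynamic of the teleport.
#' @param loss_duration Number of dynamics the displacement persists; must
#'   be long enough for the tracker to run through its miss window and
#'   recalibrate if the loss is to be recovered within the window.
#' @param offset_mm Length-3 displacement applied during the loss window.
#' @return A [trajectory()].
#' @export
trajectory_with_loss <- function(waypoints, step_mm, n_dynamics,
                                 loss_at, loss_duration, offset_mm,
                                 jitter_sd_mm = 0, seed = 1L,
                                 radius_mm = 4, brightness = 300) {
  tr <- simulate_trajectory(waypoints, step_mm, n_dynamics,
                            jitter_sd_mm = jitter_sd_mm, seed = seed,
                            radius_mm = radius_mm, brightness = brightness)
  idx <- seq.int(loss_at, min(loss_at + loss_duration - 1, n_dynamics - 1)) + 1L
  tr$positions_mm[idx, ] <- tr$positions_mm[idx, , drop = FALSE] +
    matrix(as_point3(offset_mm, "offset_mm"), nrow = length(idx), ncol = 3L,
           byrow = TRUE)
  tr
}
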