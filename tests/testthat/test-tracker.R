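test_that("stack selection keeps the brightest region across slices", {
  # balloon visible in two adjacent slices, the later one brighter: the
  # brighter slice is selected and the dimmer discarded
  segs <- list(fake_region(8, mean_intensity = 180),
               fake_region(9, mean_intensity = 240))
  det <- select_stack_region(segs)
  expect_true(det$found)
  expect_equal(det$slice_index, 9)

  expect_false(select_stack_region(list(empty_seg <- fake_region(0, 1)[0, ]))$found)

  # ties break by larger area, then lower slice index
  t1 <- select_stack_region(list(fake_region(1, 100, area = 5),
                                 fake_region(2, 100, area = 9)))
  expect_equal(t1$slice_index, 2)
  t2 <- select_stack_region(list(fake_region(2, 100, area = 5),
                                 fake_region(1, 100, area = 5)))
  expect_equal(t2$slice_index, 1)
})

test_that("stack selection equals an exhaustive argmax on random stacks", {
  withr::with_seed(61, {
    for (rep in 1:50) {
      n <- sample(1:6, 1)
      regs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        fake_region(sample(0:2, 1), mean_intensity = sample(50:60, 1),
                    area = sample(3:12, 1),
                    com_row = runif(1, 2, 30), com_col = runif(1, 2, 30))
      }))
      det <- select_stack_region(regs)
      ord <- order(-regs$mean_intensity, -regs$area_px, regs$slice_index)
      expect_equal(det$region$com_row, regs$com_row[ord[1]])
      expect_equal(det$slice_index, regs$slice_index[ord[1]])
    }
  })
})

test_that("localization round-trips from world position through imaging and back", {
  vol <- uniform_phantom()
  p <- coronal_prescription(fov = 300, matrix = 128)
  pitch <- 300 / 128
  withr::with_seed(71, {
    for (rep in 1:10) {
      truth <- c(runif(1, -40, 40), runif(1, -12, 12), runif(1, -40, 40))
      bal <- balloon_truth(truth, radius_mm = 4, brightness = 300)
      stack <- acquire_stack(vol, bal, p, "RUNTIME", noise_sd = 1, seed = rep)
      segs <- lapply(1:3, function(i) {
        segment_slice(stack$slices[[i]]$pixels, slice_index = i - 1L)
      })
      det <- select_stack_region(segs, p)
      expect_true(det$found)
      # in-plane error under one pixel pitch; through-plane is quantised to
      # the slice centre by construction
      inplane_err <- sqrt(sum((det$position_mm[c(1, 3)] - truth[c(1, 3)])^2))
      expect_lt(inplane_err, pitch)
      expect_lt(abs(det$position_mm[2] - truth[2]), p$thickness_mm / 2 + 1e-9)
    }
  })
})

test_that("outcome classification distinguishes the three cases", {
  expect_equal(classify_outcome(fake_det(1), 3)$case, "CENTRAL")
  o <- classify_outcome(fake_det(2), 3)
  expect_equal(o$case, "OUTER")
  expect_equal(o$outer_direction, 1)
  expect_equal(classify_outcome(fake_det(0), 3)$outer_direction, -1)
  expect_equal(classify_outcome(structure(list(found = FALSE),
                                          class = "stack_detection"), 3)$case,
               "NONE")
  expect_error(classify_outcome(fake_det(1), 4), "odd")
  expect_error(tracker_config(coronal_prescription(n_slices = 9),
                              coronal_prescription(n_slices = 4)), "odd")
})

test_that("the state machine follows the full mode-by-outcome transition table", {
  cal <- coronal_prescription(n_slices = 9)
  run <- coronal_prescription(n_slices = 3)
  cfg <- tracker_config(cal, run, miss_threshold = 5, latency_dynamics = 1)

  found_at <- function(pos) structure(
    list(found = TRUE, region = fake_region(1, 100), slice_index = 1L,
         position_mm = pos), class = "stack_detection")
  none <- structure(list(found = FALSE), class = "stack_detection")

  # CALIBRATION + found -> RUNTIME centred on the detection, misses reset
  st <- new_tracker_state(cfg)
  a <- advance_state(st, list(case = NA), found_at(c(3, 7, -2)),
                     stack_mode = "CALIBRATION")
  expect_equal(a$state$mode, "RUNTIME")
  expect_equal(a$state$runtime_center_mm, c(3, 7, -2))
  expect_equal(a$state$miss_count, 0L)
  expect_equal(a$emitted$mode, "RUNTIME")
  expect_equal(a$emitted$prescription$center_mm, c(3, 7, -2))

  # CALIBRATION + not found -> repeat calibration
  b <- advance_state(new_tracker_state(cfg), list(case = NA), none,
                     stack_mode = "CALIBRATION")
  expect_equal(b$state$mode, "CALIBRATION")
  expect_identical(b$emitted$prescription$center_mm, cal$center_mm)

  # RUNTIME + CENTRAL -> fixed point (emitted prescription unchanged)
  st_r <- a$state
  c1 <- advance_state(st_r, list(case = "CENTRAL"), found_at(c(3, 7, -2)),
                      stack_mode = "RUNTIME")
  expect_equal(c1$state$mode, "RUNTIME")
  expect_equal(c1$emitted$prescription$center_mm, c(3, 7, -2))

  # RUNTIME + OUTER -> shift by exactly one slice thickness along the normal
  c2 <- advance_state(st_r, list(case = "OUTER", outer_direction = +1),
                      found_at(c(3, 17, -2)), stack_mode = "RUNTIME")
  expect_equal(c2$state$runtime_center_mm - c(3, 7, -2),
               10 * run$normal)
  c2m <- advance_state(st_r, list(case = "OUTER", outer_direction = -1),
                       found_at(c(3, -3, -2)), stack_mode = "RUNTIME")
  expect_equal(c2m$state$runtime_center_mm - c(3, 7, -2), -10 * run$normal)

  # RUNTIME + NONE x miss_threshold -> revert to CALIBRATION, counter cleared
  st_m <- a$state
  for (k in 1:4) {
    r <- advance_state(st_m, list(case = "NONE"), none, stack_mode = "RUNTIME")
    st_m <- r$state
    expect_equal(st_m$mode, "RUNTIME")
    expect_equal(st_m$miss_count, k)
  }
  r5 <- advance_state(st_m, list(case = "NONE"), none, stack_mode = "RUNTIME")
  expect_equal(r5$state$mode, "CALIBRATION")
  expect_equal(r5$state$miss_count, 0L)
  expect_true(r5$state$switched_to_calibration)
  expect_equal(r5$emitted$mode, "CALIBRATION")

  # a detection resets the miss counter mid-window
  st_m2 <- advance_state(a$state, list(case = "NONE"), none,
                         stack_mode = "RUNTIME")$state
  expect_equal(st_m2$miss_count, 1L)
  st_m2 <- advance_state(st_m2, list(case = "CENTRAL"), found_at(c(3, 7, -2)),
                         stack_mode = "RUNTIME")$state
  expect_equal(st_m2$miss_count, 0L)
})

test_that("the latency queue delays prescriptions by the configured dynamics", {
  cal <- coronal_prescription(n_slices = 9)
  run <- coronal_prescription(n_slices = 3)
  cfg <- tracker_config(cal, run, latency_dynamics = 2)
  st <- new_tracker_state(cfg)
  expect_length(st$pending, 2)
  found <- structure(list(found = TRUE, region = fake_region(1, 100),
                          slice_index = 1L, position_mm = c(0, 5, 0)),
                     class = "stack_detection")
  a <- advance_state(st, list(case = NA), found, stack_mode = "CALIBRATION")
  # with latency 2 the next acquisition still uses the old calibration entry
  expect_equal(a$next_entry$mode, "CALIBRATION")
  expect_length(a$state$pending, 2)
  a2 <- advance_state(a$state, list(case = NA), found, stack_mode = "CALIBRATION")
  expect_equal(a2$next_entry$mode, "RUNTIME")
})

test_that("a static catheter at high CNR locks into Runtime immediately", {
  cond <- phantom_conditions()
  traj <- trajectory(matrix(c(0, 3, 0), 30, 3, byrow = TRUE))
  s <- run_session(cond$volume, traj, cond$detector, cond$tracker,
                   noise_sd = 2, seed = 4)
  expect_equal(s$log$mode[1], "CALIBRATION")
  expect_true(all(s$log$mode[-1] == "RUNTIME"))
  expect_true(all(s$log$outcome[-1] == "CENTRAL"))
  expect_true(all(s$log$stack_label == "TP"))
})

test_that("steady through-plane motion is tracked by alternating shifts without loss", {
  cond <- phantom_conditions()
  # half-thickness steps: worst admissible per-dynamic motion
  traj <- simulate_trajectory(list(c(0, -30, 0), c(0, 30, 0), c(0, -30, 0)),
                              step_mm = 5, n_dynamics = 25, jitter_sd_mm = 0)
  s <- run_session(cond$volume, traj, cond$detector, cond$tracker,
                   noise_sd = 2, seed = 9)
  expect_true(all(s$log$truth_in_slab))
  expect_true(all(s$log$found))
  expect_gt(sum(s$log$outcome == "OUTER", na.rm = TRUE), 0)
  # every applied shift is exactly one slice thickness along the normal
  applied <- diff(s$log$stack_center_y[s$log$mode == "RUNTIME"])
  expect_true(all(abs(applied[applied != 0]) == 10))
  # in-plane centre components never move in Runtime mode
  expect_equal(length(unique(s$log$stack_center_x[s$log$mode == "RUNTIME"])), 1)
  expect_equal(length(unique(s$log$stack_center_z[s$log$mode == "RUNTIME"])), 1)
})

test_that("a teleported balloon triggers exactly five misses, revert and recovery", {
  cond <- phantom_conditions()
  traj <- trajectory_with_loss(list(c(0, -10, 0), c(0, 10, 0), c(0, -10, 0)),
                               step_mm = 2, n_dynamics = 70,
                               loss_at = 50, loss_duration = 20,
                               offset_mm = c(0, 30, 0))
  s <- run_session(cond$volume, traj, cond$detector, cond$tracker,
                   noise_sd = 2, seed = 13)
  lg <- s$log
  expect_equal(lg$outcome[lg$dynamic %in% 50:54], rep("NONE", 5))
  expect_true(lg$switch_to_calibration[lg$dynamic == 54])
  expect_equal(lg$mode[lg$dynamic == 55], "CALIBRATION")
  expect_true(lg$found[lg$dynamic == 55])
  expect_equal(lg$mode[lg$dynamic == 56], "RUNTIME")
  st <- session_statistics(s)
  expect_equal(st$correct_switch_fraction, 1)
})
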