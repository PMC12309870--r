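test_that("uniform phantom carries tissue_level everywhere in the body", {
  vol <- build_phantom(c(24, 24, 24), tissue_level = 100, spacing_mm = 2,
                       body_margin_mm = 0)
  expect_true(all(vol$intensities == 100))
  vol2 <- build_phantom(c(24, 24, 24), tissue_level = 100, spacing_mm = 2,
                        body_margin_mm = 6)
  expect_setequal(unique(as.vector(vol2$intensities)), c(0, 100))
})

test_that("tube primitive matches a brute-force point-in-tube test", {
  spec <- list(list(type = "tube", from = c(0, 0, -30), to = c(0, 0, 30),
                    radius_mm = 5, intensity = 200))
  vol <- build_phantom(c(16, 16, 16), vessel_spec = spec, tissue_level = 100,
                       spacing_mm = 3, body_margin_mm = 0)
  d <- dim(vol$intensities)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    w <- vol$origin_mm + (c(i, j, k) - 1) * vol$spacing_mm
    # axis along z through (0, 0): in-tube iff radial distance <= 5 and the
    # axial projection falls within the clamped segment
    t <- max(min((w[3] + 30) / 60, 1), 0)
    dist <- sqrt(w[1]^2 + w[2]^2 + (w[3] - (-30 + 60 * t))^2)
    expected <- if (dist <= 5) 200 else 100
    expect_identical(unname(vol$intensities[i, j, k]), expected)
  }
})

test_that("phantom construction is deterministic for a fixed seed", {
  a <- build_phantom(c(16, 16, 16), tissue_level = 50, texture_sd = 0.1, seed = 7)
  b <- build_phantom(c(16, 16, 16), tissue_level = 50, texture_sd = 0.1, seed = 7)
  c <- build_phantom(c(16, 16, 16), tissue_level = 50, texture_sd = 0.1, seed = 8)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("trajectory interpolation follows the waypoints at constant speed", {
  tr0 <- simulate_trajectory(list(c(1, 2, 3), c(9, 9, 9)), step_mm = 0,
                             n_dynamics = 5)
  expect_true(all(tr0$positions_mm == matrix(c(1, 2, 3), 5, 3, byrow = TRUE)))

  tr <- simulate_trajectory(list(c(0, 0, 0), c(0, 0, 100)), step_mm = 10,
                            n_dynamics = 5)
  expect_equal(tr$positions_mm[, 3], c(0, 10, 20, 30, 40))
  expect_true(all(tr$positions_mm[, 1:2] == 0))

  # clamped at the final waypoint
  tr2 <- simulate_trajectory(list(c(0, 0, 0), c(0, 0, 10)), step_mm = 8,
                             n_dynamics = 4)
  expect_equal(tr2$positions_mm[, 3], c(0, 8, 10, 10))
})

test_that("jittered trajectories match a direct Monte-Carlo oracle", {
  n <- 1000
  tr <- simulate_trajectory(list(c(0, 0, 0), c(0, 0, 1)), step_mm = 0,
                            n_dynamics = n, jitter_sd_mm = 1, seed = 42)
  disp <- sqrt(rowSums(diff(tr$positions_mm)^2))
  # oracle: mean step length of a static point with iid N(0,1) jitter,
  # estimated by independent simulation
  oracle <- withr::with_seed(999, {
    reps <- matrix(rnorm(3 * 20000), ncol = 3)
    sqrt(rowSums((reps[seq(1, 19999, 2), ] - reps[seq(2, 20000, 2), ])^2))
  })
  se <- sqrt(var(disp) / length(disp) + var(oracle) / length(oracle))
  expect_lt(abs(mean(disp) - mean(oracle)), 3 * se)
})

test_that("partial-volume weight implements normalised interval overlap", {
  expect_equal(partial_volume_weight(0, radius_mm = 4, thickness_mm = 10), 1)
  expect_equal(partial_volume_weight(0, radius_mm = 5, thickness_mm = 10), 1)
  expect_equal(partial_volume_weight(9.1, radius_mm = 4, thickness_mm = 10), 0)
  expect_equal(partial_volume_weight(5, radius_mm = 2.5, thickness_mm = 10), 0.5)
  # symmetric in offset sign, and equal to a fine-grid overlap oracle
  for (off in c(0, 1.3, 4.9, 6.2, 8)) {
    w <- partial_volume_weight(off, 4, 10)
    expect_equal(w, partial_volume_weight(-off, 4, 10))
    pts <- seq(off - 4 + 1e-7, off + 4 - 1e-7, length.out = 200001)
    expect_equal(w, mean(abs(pts) <= 5), tolerance = 1e-4)
  }
})

test_that("partial-volume weights over a covering stack conserve the interval", {
  # slabs of a contiguous stack partition the through-plane axis, so the
  # weights of a balloon fully covered by the stack sum to exactly 1
  for (r in c(2, 4, 7)) for (T in c(6, 10)) for (pos in c(0, 2.7, -5.3)) {
    offsets <- seq(-50, 50, by = T)  # slice centres of a wide stack
    w <- vapply(offsets, function(sc) partial_volume_weight(pos - sc, r, T),
                numeric(1))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("slice formation follows the saturation-contrast model", {
  vol <- uniform_phantom(level = 100)
  p <- coronal_prescription(fov = 200, matrix = 64)
  # 90 degree prep, no balloon in slab: fully saturated, exactly zero
  s90 <- sample_slice(vol, balloon_truth(c(0, 100, 0)), p, 1, 90)
  expect_true(all(s90$pixels == 0))
  # 50 degree prep on a uniform phantom: constant at 100 cos(50) ~ 64.3
  s50 <- sample_slice(vol, NULL, p, 1, 50)
  expect_equal(max(abs(s50$pixels - 100 * cos(50 * pi / 180))), 0,
               tolerance = 1e-9)
  expect_equal(s50$pixels[1, 1], 64.27876, tolerance = 1e-5)
})

test_that("balloon signal dilutes with through-plane offset per the overlap integral", {
  vol <- uniform_phantom(level = 100)
  # odd matrix: one pixel sits exactly at the slice centre, so the image
  # peak equals brightness x weight with no in-plane discretisation loss
  p <- coronal_prescription(fov = 300, matrix = 75)
  peak_at <- function(y) {
    s <- sample_slice(vol, balloon_truth(c(0, y, 0), radius_mm = 4,
                                         brightness = 300), p, 1, 90)
    max(s$pixels)
  }
  w_oracle <- function(off) {
    pts <- seq(off - 4 + 1e-7, off + 4 - 1e-7, length.out = 100001)
    mean(abs(pts) <= 5)
  }
  expect_equal(peak_at(0), 300 * w_oracle(0), tolerance = 1e-6)
  expect_equal(peak_at(5), 300 * w_oracle(5), tolerance = 1e-3)
  expect_gt(peak_at(0), peak_at(5))  # centred beats slab edge
  expect_equal(peak_at(9.5), 0)      # outside the slab: no signal, no error
})

test_that("stack acquisition honours mode defaults and is reproducible", {
  vol <- uniform_phantom()
  bal <- balloon_truth(c(0, 0, 0))
  cal <- coronal_prescription(n_slices = 9)
  run <- coronal_prescription(n_slices = 3)
  sc <- acquire_stack(vol, bal, cal, "CALIBRATION", noise_sd = 3, seed = 5)
  expect_length(sc$slices, 9)
  expect_equal(sc$prep_angle_deg, 90)
  sr <- acquire_stack(vol, bal, run, "RUNTIME", noise_sd = 3, seed = 5)
  expect_length(sr$slices, 3)
  expect_equal(sr$prep_angle_deg, 50)

  sr2 <- acquire_stack(vol, bal, run, "RUNTIME", noise_sd = 3, seed = 5)
  for (i in 1:3) expect_identical(sr$slices[[i]]$pixels, sr2$slices[[i]]$pixels)
  # different slices draw independent noise
  expect_false(identical(sr$slices[[1]]$pixels - sr$slices[[2]]$pixels,
                         matrix(0, 128, 128)))
})

test_that("NIfTI round trip preserves volume, spacing and origin", {
  vol <- build_phantom(c(16, 16, 16), tissue_level = 80, spacing_mm = c(2, 3, 4),
                      texture_sd = 0.05, seed = 3)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, path)
  back <- read_volume_nifti(path)
  expect_equal(back$intensities, vol$intensities, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$spacing_mm, vol$spacing_mm, tolerance = 1e-6)
  expect_equal(back$origin_mm, vol$origin_mm, tolerance = 1e-4)
})
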