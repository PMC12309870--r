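test_that("stack truth retains the brightest slice's truth region", {
  mask <- matrix(FALSE, 16, 16); mask[8:9, 8:9] <- TRUE
  empty <- matrix(FALSE, 16, 16)
  img_dim <- matrix(50, 16, 16); img_bright <- matrix(90, 16, 16)
  # truth in slices 8 and 9 (0-based), slice 9 brighter -> slice 9 retained
  masks <- c(rep(list(empty), 8), list(mask), list(mask))
  imgs <- c(rep(list(img_dim), 9), list(img_bright))
  st <- stack_truth(masks, imgs)
  expect_equal(st$slice_index, 9L)
  expect_identical(st$mask, mask)

  expect_equal(stack_truth(list(mask, empty), list(img_dim, img_dim))$slice_index, 0L)
  expect_true(is.na(stack_truth(list(empty, empty), list(img_dim, img_dim))$slice_index))
})

test_that("stack truth follows the partial-volume weight argmax on simulated stacks", {
  vol <- uniform_phantom()
  p <- coronal_prescription()
  withr::with_seed(81, {
    for (rep in 1:5) {
      y <- runif(1, -12, 12)
      bal <- balloon_truth(c(0, y, 0), radius_mm = 4, brightness = 300)
      stack <- acquire_stack(vol, bal, p, "RUNTIME", noise_sd = 0.5, seed = rep)
      masks <- lapply(0:2, function(i) truth_slice_mask(bal, p, i))
      st <- stack_truth(masks, lapply(stack$slices, `[[`, "pixels"))
      w <- vapply(0:2, function(i) {
        partial_volume_weight(y - slice_centers(p)[i + 1, 2], 4, 10)
      }, numeric(1))
      expect_equal(st$slice_index, which.max(w) - 1L)
    }
  })
})

test_that("slice labelling implements the centre-of-mass intersection rule", {
  empty_mask <- matrix(FALSE, 32, 32)
  truth <- empty_mask; truth[10:14, 10:14] <- TRUE
  no_regions <- classical_segment(matrix(1, 32, 32))
  img <- matrix(100, 32, 32)

  expect_equal(label_slice(no_regions, empty_mask, img), "TN")
  expect_equal(label_slice(no_regions, truth, img), "FN")
  expect_equal(label_slice(fake_region(0, 50, com_row = 12, com_col = 12),
                           empty_mask, img), "FP")
  expect_equal(label_slice(fake_region(0, 50, com_row = 12, com_col = 12),
                           truth, img), "TP")
  # region far from the truth: one FN, verified by direct membership
  far <- fake_region(0, 50, com_row = 30, com_col = 30)
  expect_false(truth[30, 30])
  expect_equal(label_slice(far, truth, img), "FN")
  # several regions: the brightest one is the slice's detection
  two <- dplyr::bind_rows(fake_region(0, 90, com_row = 30, com_col = 30),
                          fake_region(0, 40, com_row = 12, com_col = 12))
  expect_equal(label_slice(two, truth, img), "FN")
})

test_that("stack labelling also requires the slice index to match", {
  truth_mask <- matrix(FALSE, 32, 32); truth_mask[9:11, 9:11] <- TRUE
  truth <- list(slice_index = 9L, mask = truth_mask)
  none <- structure(list(found = FALSE), class = "stack_detection")
  hit <- function(slice, r = 10, c = 10) structure(
    list(found = TRUE, region = fake_region(slice, 100, com_row = r, com_col = c),
         slice_index = as.integer(slice), position_mm = c(0, 0, 0)),
    class = "stack_detection")

  expect_equal(label_stack(hit(9), truth), "TP")
  expect_equal(label_stack(hit(8), truth), "FN")        # wrong slice
  expect_equal(label_stack(hit(9, 30, 30), truth), "FN")  # mislocalized
  expect_equal(label_stack(none, truth), "FN")
  expect_equal(label_stack(none, list(slice_index = NA_integer_, mask = NULL)), "TN")
  expect_equal(label_stack(hit(9), list(slice_index = NA_integer_, mask = NULL)), "FP")
})

test_that("scores follow the standard confusion-matrix definitions", {
  perfect <- score_detections(c(rep("TP", 9), "TN"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  mixed <- score_detections(c(rep("TP", 91), rep("FN", 9),
                              rep("TN", 96), rep("FP", 4)))
  expect_equal(mixed$sensitivity, 0.91)
  expect_equal(mixed$specificity, 0.96)
  expect_equal(mixed$accuracy, 187 / 200)
  expect_equal(mixed$tp + mixed$fp + mixed$fn + mixed$tn, 200)

  shuffled <- withr::with_seed(5, sample(c(rep("TP", 91), rep("FN", 9),
                                           rep("TN", 96), rep("FP", 4))))
  expect_identical(score_detections(shuffled), mixed)

  # undefined ratios stay absent, never zero
  only_neg <- score_detections(rep("TN", 10))
  expect_true(is.na(only_neg$sensitivity))
  expect_equal(only_neg$specificity, 1)
})

test_that("CNR matches the closed form on constructed images", {
  img <- matrix(100, 40, 40)
  truth <- matrix(FALSE, 40, 40); truth[19:22, 19:22] <- TRUE
  withr::with_seed(91, {
    img <- img + matrix(rnorm(1600, 0, 5), 40, 40)
  })
  img[truth] <- 200
  rec <- compute_cnr(img, truth)
  bg_sd <- rec$background_sd
  expect_equal(rec$balloon_mean, 200)
  expect_equal(rec$cnr, (200 - rec$background_mean) / bg_sd)
  expect_equal(rec$cnr, 20, tolerance = 0.25 * 20)  # sd estimated from ~5

  # zero contrast -> zero CNR; doubling intensities preserves both ratios
  # background variation placed inside the 5-10 px annulus around the truth
  flat_noise <- matrix(100, 40, 40)
  flat_noise[11, 15:25] <- 99; flat_noise[30, 15:25] <- 101
  rec0 <- compute_cnr(flat_noise, truth)
  expect_equal(rec0$cnr, 0, tolerance = 1e-9)
  rec1 <- compute_cnr(img, truth)
  rec2 <- compute_cnr(2 * img, truth)
  expect_equal(rec2$cnr, rec1$cnr, tolerance = 1e-9)
  expect_equal(rec2$rel_contrast_pct, rec1$rel_contrast_pct, tolerance = 1e-9)

  expect_error(compute_cnr(img, matrix(FALSE, 40, 40)), "nonempty")
})

test_that("Welch comparison separates CNR groups and stays calibrated under the null", {
  # power: well-separated groups give p < 0.001 in most replicates
  pow <- withr::with_seed(101, {
    vapply(1:40, function(i) {
      rec <- tibble::tibble(cnr = c(rnorm(50, 20, 1), rnorm(50, 10, 1)),
                            label = rep(c("TP", "FN"), each = 50))
      out <- suppressWarnings(compare_cnr_groups(rec))  # no FP group here
      expect_gt(out$groups$mean_cnr[out$groups$label == "TP"],
                out$groups$mean_cnr[out$groups$label == "FN"])
      out$comparisons$p_value[out$comparisons$comparison == "TP vs FN"]
    }, numeric(1))
  })
  expect_gte(mean(pow < 0.001), 0.95)

  # type-I calibration: identical groups reject at ~alpha
  null_p <- withr::with_seed(103, {
    vapply(1:1000, function(i) {
      rec <- tibble::tibble(cnr = rnorm(40, 15, 3),
                            label = rep(c("TP", "FN"), each = 20))
      suppressWarnings(compare_cnr_groups(rec))$comparisons$p_value[1]
    }, numeric(1))
  })
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  # label swap leaves the p-value unchanged
  rec <- tibble::tibble(cnr = c(rnorm(20, 20, 2), rnorm(20, 12, 2)),
                        label = rep(c("TP", "FN"), each = 20))
  swapped <- rec
  swapped$label <- ifelse(rec$label == "TP", "FN", "TP")
  expect_equal(suppressWarnings(compare_cnr_groups(rec))$comparisons$p_value[1],
               suppressWarnings(compare_cnr_groups(swapped))$comparisons$p_value[1])

  # undersized groups are skipped with a warning (both comparisons here)
  w <- testthat::capture_warnings(
    out <- compare_cnr_groups(tibble::tibble(cnr = c(1, 2, 3),
                                             label = c("TP", "TP", "FN"))))
  expect_true(all(grepl("skipped", w)) && length(w) == 2)
  expect_equal(nrow(out$comparisons), 0)
})

test_that("session statistics are recomputable from a hand-built log", {
  log <- tibble::tibble(
    dynamic = 0:9,
    mode = c("CALIBRATION", rep("RUNTIME", 9)),
    truth_in_slab = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      TRUE, TRUE),
    switch_to_calibration = c(rep(FALSE, 7), TRUE, FALSE, FALSE))
  st <- session_statistics(log, miss_threshold = 5)
  expect_equal(st$runtime_fraction, 0.9)
  expect_equal(st$calibration_fraction, 0.1)
  expect_equal(st$switch_count, 1)
  expect_equal(st$correct_switch_fraction, 1)  # window 3..7 all out of slab

  # same log, but the balloon was still in the slab mid-window: incorrect
  log2 <- log
  log2$truth_in_slab[5] <- TRUE
  expect_equal(session_statistics(log2, 5)$correct_switch_fraction, 0)

  log3 <- log
  log3$switch_to_calibration[8] <- FALSE
  expect_true(is.na(session_statistics(log3, 5)$correct_switch_fraction))
  expect_equal(session_statistics(log3, 5)$switch_count, 0)
})
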