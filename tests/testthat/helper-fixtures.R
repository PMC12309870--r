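# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

# Uniform water-bath phantom large enough that a 300 mm FOV slice stays
# inside the body (flat background for detector-sensitive tests).
uniform_phantom <- function(level = 100, shape = 48, spacing = 8) {
  build_phantom(rep(shape, 3), tissue_level = level, spacing_mm = spacing,
                body_margin_mm = 0)
}

coronal_prescription <- function(center = c(0, 0, 0), n_slices = 3,
                                 thickness = 10, fov = 300, matrix = 128) {
  slice_prescription(center, normal = c(0, 1, 0), n_slices = n_slices,
                     thickness_mm = thickness, fov_mm = c(fov, fov),
                     matrix = c(matrix, matrix))
}

# High-CNR study conditions used by the closed-loop tests (the phantom
# preset, rebuilt in code so tests do not depend on the YAML).
phantom_conditions <- function(seed = 1, n_dynamics = 100) {
  cfg <- preset_config("phantom")
  cfg$seed <- as.integer(seed)
  cfg$trajectory$n_dynamics <- n_dynamics
  list(
    cfg = cfg,
    volume = cathtrack:::build_phantom_from_config(cfg),
    trajectory = cathtrack:::build_trajectory_from_config(cfg),
    detector = cathtrack:::build_detector_from_config(cfg),
    tracker = cathtrack:::build_tracker_from_config(cfg))
}

# ---- independent oracles --------------------------------------------------

# Brute-force segmentation oracle: explicit threshold + recursive flood
# fill with a pixel stack, written independently of the package's
# labelling. Returns regions as a list of data.frames sorted canonically.
oracle_segment <- function(image, z_threshold = 5, min_area = 3,
                           max_area = 400) {
  med <- stats::median(image)
  scale <- stats::mad(image)
  sdv <- stats::sd(image)
  if (scale < 0.1 * sdv) scale <- sdv
  if (is.na(scale) || scale == 0) return(list())
  mask <- (image - med) / scale >= z_threshold
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  regions <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    px <- NULL
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      px <- rbind(px, p)
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    if (nrow(px) >= min_area && nrow(px) <= max_area) {
      vals <- image[px]
      regions[[length(regions) + 1L]] <- data.frame(
        area = nrow(px),
        mean_intensity = mean(vals),
        com_row = sum(px[, 1] * vals) / sum(vals),
        com_col = sum(px[, 2] * vals) / sum(vals))
    }
  }
  regions
}

# canonical sort for comparing region sets
sort_regions <- function(df) df[order(df$com_row, df$com_col), , drop = FALSE]

oracle_region_table <- function(image, ...) {
  regs <- oracle_segment(image, ...)
  if (!length(regs)) {
    return(data.frame(area = integer(), mean_intensity = numeric(),
                      com_row = numeric(), com_col = numeric()))
  }
  sort_regions(do.call(rbind, regs))
}

package_region_table <- function(seg) {
  if (!nrow(seg)) {
    return(data.frame(area = integer(), mean_intensity = numeric(),
                      com_row = numeric(), com_col = numeric()))
  }
  sort_regions(data.frame(area = seg$area_px,
                          mean_intensity = seg$mean_intensity,
                          com_row = seg$com_row, com_col = seg$com_col))
}

# random multi-blob test image on a noisy background
random_blob_image <- function(nr = 32, nc = 32, n_blobs = NULL) {
  img <- matrix(rnorm(nr * nc, 100, 5), nr, nc)
  if (is.null(n_blobs)) n_blobs <- sample(0:3, 1)
  for (b in seq_len(n_blobs)) {
    ctr <- c(runif(1, 5, nr - 4), runif(1, 5, nc - 4))
    sg <- runif(1, 1, 2.5)
    amp <- runif(1, 60, 300)
    R <- outer(seq_len(nr) - ctr[1], rep(1, nc))
    C <- outer(rep(1, nr), seq_len(nc) - ctr[2])
    img <- img + amp * exp(-(R^2 + C^2) / (2 * sg^2))
  }
  img
}

# fabricate a one-row region table (for selection/label tests)
fake_region <- function(slice_index, mean_intensity, area = 10,
                        com_row = 10, com_col = 10, peak = NULL) {
  tibble::tibble(slice_index = as.integer(slice_index),
                 area_px = as.integer(area),
                 mean_intensity = mean_intensity,
                 peak_intensity = peak %||% (mean_intensity * 1.5),
                 com_row = com_row, com_col = com_col,
                 pixels = list(cbind(row = com_row, col = com_col)),
                 region_id = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# found-detection stub in a given slice
fake_det <- function(slice_index) {
  structure(list(found = TRUE, region = fake_region(slice_index, 100),
                 slice_index = as.integer(slice_index),
                 position_mm = c(0, 0, 0)),
            class = "stack_detection")
}

# small semi-artificial dataset on flat noisy backgrounds (for network tests)
small_training_set <- function(n_bg = 4, size = 48, per_bg = 12, seed = 1) {
  bgs <- withr::with_seed(seed, {
    lapply(seq_len(n_bg), function(i) {
      matrix(64 + rnorm(size * size, 0, 2), size, size)
    })
  })
  generate_training_set(bgs, per_bg, seed = seed)
}
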