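#' Detector configuration
#'
#' The tracking framework is detector-agnostic: any backend that turns a 2D
#' image into candidate regions can drive it. Two backends ship with the
#' package: `"CLASSICAL"`, a deterministic robust-threshold detector
#' (median/MAD z-score, 4-connected components, area filter) that needs no
#' training, and `"UNET"`, a small trainable encoder-decoder segmentation
#' network (see [train_unet()]).
#'
#' @param backend `"CLASSICAL"` (default) or `"UNET"`.
#' @param z_threshold Robust z-score cutoff for the classical backend.
#' @param min_area_px,max_area_px Region area limits (pixels); candidates
#'   outside `[min_area_px, max_area_px]` are discarded by every backend.
#' @param model A trained model handle from [train_unet()] (UNET only).
#' @param prob_threshold Pixel probability cutoff for the UNET backend;
#'   defaults to the threshold calibrated on the validation split during
#'   [train_unet()] (falling back to 0.5).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(backend = c("CLASSICAL", "UNET"),
                            z_threshold = 5, min_area_px = 3L,
                            max_area_px = 400L, model = NULL,
                            prob_threshold = NULL) {
  backend <- match.arg(backend)
  if (min_area_px < 1L) abort("`min_area_px` must be >= 1.")
  if (max_area_px <= min_area_px) abort("`max_area_px` must exceed `min_area_px`.")
  if (backend == "UNET" && is.null(model)) {
    abort("UNET backend requested but no trained `model` supplied; train one with train_unet().")
  }
  structure(list(backend = backend, z_threshold = z_threshold,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 model = model, prob_threshold = prob_threshold),
            class = "detector_config")
}

# 4-connected component labelling by frontier expansion over foreground
# pixels. Returns an integer matrix of labels (0 = background). Label order
# follows column-major scan order of the first pixel of each component,
# which makes the output invariant to how the mask was produced.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  cur <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- start
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
              frontier[c > 1L] - nr, frontier[c < nc] + nr)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# Per-region summary rows for a label image. COM is intensity-weighted.
regions_from_labels <- function(labels, image, slice_index,
                                min_area = 1L, max_area = Inf) {
  n <- max(labels)
  if (n == 0L) return(empty_segmentation(slice_index))
  nr <- nrow(labels)
  rows <- lapply(seq_len(n), function(k) {
    idx <- which(labels == k)
    area <- length(idx)
    if (area < min_area || area > max_area) return(NULL)
    r <- (idx - 1L) %% nr + 1L
    c <- (idx - 1L) %/% nr + 1L
    wgt <- image[idx]
    tw <- sum(wgt)
    if (tw <= 0) { wgt <- rep(1, area); tw <- area }
    tibble::tibble(
      slice_index = as.integer(slice_index),
      area_px = area,
      mean_intensity = mean(image[idx]),
      peak_intensity = max(image[idx]),
      com_row = sum(r * wgt) / tw,
      com_col = sum(c * wgt) / tw,
      pixels = list(cbind(row = r, col = c)))
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_segmentation(slice_index))
  out$region_id <- seq_len(nrow(out))
  class(out) <- c("slice_segmentation", class(out))
  out
}

empty_segmentation <- function(slice_index = 0L) {
  out <- tibble::tibble(
    slice_index = integer(), area_px = integer(), mean_intensity = numeric(),
    peak_intensity = numeric(), com_row = numeric(), com_col = numeric(),
    pixels = list(), region_id = integer())
  class(out) <- c("slice_segmentation", class(out))
  out
}

#' Classical balloon segmentation of one slice
#'
#' Deterministic baseline detector: each pixel's robust z-score is computed
#' against the image median and MAD (falling back to the SD when the MAD is
#' zero, and returning an empty segmentation when the image is constant);
#' pixels with `z >= z_threshold` form the candidate mask, which is split
#' into 4-connected components and filtered by area.
#'
#' @param image Numeric matrix (one 2D slice).
#' @param z_threshold Robust z cutoff (default 5).
#' @param min_area_px,max_area_px Area limits in pixels.
#' @param slice_index 0-based slice index recorded in the output.
#' @return A `slice_segmentation` tibble: one row per candidate region with
#'   columns `slice_index`, `region_id`, `area_px`, `mean_intensity`,
#'   `peak_intensity`, `com_row`, `com_col` (1-based, intensity-weighted)
#'   and a `pixels` list-column of `(row, col)` index matrices.
#' @export
classical_segment <- function(image, z_threshold = 5, min_area_px = 3L,
                              max_area_px = 400L, slice_index = 0L) {
  if (any(!is.finite(image))) abort("`image` must be finite.")
  med <- median(image)
  scale <- mad(image)
  sdv <- sd(image)
  # The MAD collapses on images whose background holds a point mass at one
  # value — e.g. a fully saturated background clipped at zero, where over
  # half the pixels are exactly 0 — and then grossly underestimates the
  # noise scale. Fall back to the SD whenever the MAD is zero or
  # implausibly small relative to it.
  if (scale < 0.1 * sdv) scale <- sdv
  if (is.na(scale) || scale == 0) return(empty_segmentation(slice_index))
  mask <- (image - med) / scale >= z_threshold
  regions_from_labels(label_components(mask), image, slice_index,
                      min_area = min_area_px, max_area = max_area_px)
}

#' Segment one slice with the configured backend
#'
#' Uniform entry point for slice-based segmentation: dispatches to
#' [classical_segment()] or to the trained network, then applies the
#' config's area filter. Regions returned by any backend are pairwise
#' disjoint 4-connected components.
#'
#' @param image Numeric matrix.
#' @param config A [detector_config()].
#' @param slice_index 0-based slice index recorded in the output.
#' @return A `slice_segmentation` tibble (see [classical_segment()]).
#' @export
segment_slice <- function(image, config = detector_config(),
                          slice_index = 0L) {
  stopifnot(inherits(config, "detector_config"))
  switch(config$backend,
    CLASSICAL = classical_segment(image, config$z_threshold,
                                  config$min_area_px, config$max_area_px,
                                  slice_index),
    UNET = {
      prob <- unet_predict(config$model, image)
      thr <- config$prob_threshold %||%
        config$model$suggested_threshold %||% 0.5
      regions_from_labels(label_components(prob >= thr),
                          image, slice_index,
                          min_area = config$min_area_px,
                          max_area = config$max_area_px)
    })
}
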