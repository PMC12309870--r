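#' Stack-level ground truth from per-slice truth masks
#'
#' Mirrors how stack-based ground truth is produced for evaluation: among
#' the slices whose truth mask is nonempty, only the one whose truth region
#' has the highest mean image intensity is retained; the balloon's
#' appearances in adjacent slices are discarded. Empty truth everywhere
#' gives an empty stack truth.
#'
#' @param truth_masks List of logical matrices, one per slice (possibly
#'   all-`FALSE`).
#' @param images List of numeric matrices matching `truth_masks`.
#' @return List with `slice_index` (0-based, or `NA` when empty) and
#'   `mask` (the retained truth mask, or `NULL`).
#' @export
stack_truth <- function(truth_masks, images) {
  stopifnot(length(truth_masks) == length(images))
  nonempty <- which(vapply(truth_masks, any, logical(1)))
  if (!length(nonempty)) return(list(slice_index = NA_integer_, mask = NULL))
  means <- vapply(nonempty, function(i) {
    mean(images[[i]][truth_masks[[i]]])
  }, numeric(1))
  keep <- nonempty[which.max(means)]
  list(slice_index = keep - 1L, mask = truth_masks[[keep]])
}

# Rounded COM of the evaluated region, clamped into the image, tested for
# membership in the truth mask.
com_in_mask <- function(region, mask) {
  r <- min(max(round(region$com_row), 1L), nrow(mask))
  c <- min(max(round(region$com_col), 1L), ncol(mask))
  isTRUE(mask[r, c])
}

#' Label one slice's segmentation against its truth mask
#'
#' A true positive is a segmented region whose centre of mass intersects
#' the ground-truth region. When a slice yields several candidate regions,
#' the highest-mean-intensity one is the slice's detection (matching the
#' stack-selection rule). A mislocalized detection on a truth-containing
#' slice counts as a single FN, keeping one label per evaluated unit.
#'
#' @param segmentation A `slice_segmentation` tibble.
#' @param truth_mask Logical matrix (the slice's ground truth; may be
#'   all-`FALSE`).
#' @param image The slice image (used to rank multiple regions).
#' @return One of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
label_slice <- function(segmentation, truth_mask, image) {
  has_truth <- any(truth_mask)
  if (!nrow(segmentation)) return(if (has_truth) "FN" else "TN")
  if (!has_truth) return("FP")
  best <- segmentation[order(-segmentation$mean_intensity,
                             -segmentation$area_px,
                             segmentation$slice_index)[1L], ]
  if (com_in_mask(best, truth_mask)) "TP" else "FN"
}

#' Label a stack-level detection against the stack truth
#'
#' Same contract as [label_slice()], applied to the single selected region
#' and the single retained truth region; for a TP the detection must also
#' land in the same slice as the retained truth.
#'
#' @param detection A `stack_detection` from [select_stack_region()].
#' @param truth Output of [stack_truth()].
#' @return One of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
label_stack <- function(detection, truth) {
  has_truth <- !is.na(truth$slice_index)
  if (!detection$found) return(if (has_truth) "FN" else "TN")
  if (!has_truth) return("FP")
  if (detection$slice_index != truth$slice_index) return("FN")
  if (com_in_mask(detection$region, truth$mask)) "TP" else "FN"
}

#' Confusion-matrix scores for detection labels
#'
#' Counts TP/FP/FN/TN and computes accuracy `(TP+TN)/total`, sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`. Ratios whose denominator is
#' zero are reported as `NA` (absent), never as 0. If grouping columns are
#' supplied (for example `mode` and `level`), scores are reported per
#' group.
#'
#' @param labels Character vector of labels, or a data frame with a
#'   `label` column plus optional grouping columns.
#' @param ... Grouping columns (tidy-select), when `labels` is a data
#'   frame.
#' @return A tibble with counts and the three ratios.
#' @examples
#' score_detections(c(rep("TP", 91), rep("FN", 9), rep("TN", 96), rep("FP", 4)))
#' @export
score_detections <- function(labels, ...) {
  if (is.character(labels)) labels <- tibble::tibble(label = labels)
  if (!nrow(labels)) abort("no labels to score.")
  bad <- setdiff(unique(labels$label), c("TP", "FP", "FN", "TN"))
  if (length(bad)) abort(sprintf("unknown labels: %s", paste(bad, collapse = ", ")))
  labels |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      tp = sum(.data$label == "TP"), fp = sum(.data$label == "FP"),
      fn = sum(.data$label == "FN"), tn = sum(.data$label == "TN"),
      accuracy = (.data$tp + .data$tn) / dplyr::n(),
      sensitivity = ifelse(.data$tp + .data$fn > 0,
                           .data$tp / (.data$tp + .data$fn), NA_real_),
      specificity = ifelse(.data$tn + .data$fp > 0,
                           .data$tn / (.data$tn + .data$fp), NA_real_),
      .groups = "drop")
}

#' Balloon-to-background contrast-to-noise ratio of one slice
#'
#' CNR is `(balloon_mean - background_mean) / background_sd`, with the
#' balloon statistics taken over the truth mask and the background over an
#' annulus a configurable dilation band away from the truth region
#' (default 5-10 px, truth excluded). The relative contrast
#' `100 * (balloon_mean - background_mean) / background_mean` is reported
#' alongside.
#'
#' @param image Numeric matrix.
#' @param truth_mask Nonempty logical matrix.
#' @param annulus_px Length-2 band `(inner, outer)` in pixels from the
#'   truth region.
#' @param label Optional detection label to attach (for stratified
#'   analysis).
#' @return One-row tibble: `balloon_mean`, `background_mean`,
#'   `background_sd`, `cnr`, `rel_contrast_pct`, `label`.
#' @export
compute_cnr <- function(image, truth_mask, annulus_px = c(5, 10),
                        label = NA_character_) {
  if (!any(truth_mask)) abort("`truth_mask` must be nonempty.")
  idx <- which(truth_mask)
  nr <- nrow(image)
  tr <- (idx - 1L) %% nr + 1L
  tc <- (idx - 1L) %/% nr + 1L
  all_idx <- seq_len(length(image))
  ar <- (all_idx - 1L) %% nr + 1L
  ac <- (all_idx - 1L) %/% nr + 1L
  # distance from every pixel to the nearest truth pixel
  d2 <- outer(ar, tr, function(a, b) (a - b)^2) +
    outer(ac, tc, function(a, b) (a - b)^2)
  dmin <- sqrt(apply(d2, 1L, min))
  bg <- dmin > annulus_px[1] & dmin <= annulus_px[2] & !truth_mask[all_idx]
  if (sum(bg) < 2L) abort("degenerate background annulus.")
  bmean <- mean(image[idx])
  gmean <- mean(image[bg])
  gsd <- sd(image[bg])
  tibble::tibble(
    balloon_mean = bmean, background_mean = gmean, background_sd = gsd,
    cnr = if (gsd > 0) (bmean - gmean) / gsd else NA_real_,
    rel_contrast_pct = if (gmean != 0) 100 * (bmean - gmean) / gmean else NA_real_,
    label = label)
}

#' Compare CNR between detection-label groups
#'
#' Reports mean, SD and count of CNR per label group and two-sided Welch
#' t-tests for the stratified comparisons TP vs FN and TP vs FP (failure
#' modes are expected at lower balloon/background CNR than successes).
#' Comparisons with fewer than 2 records in either group are skipped with
#' a warning.
#'
#' @param records Tibble with columns `cnr` and `label` (rows from
#'   [compute_cnr()]).
#' @return List with `groups` (tibble of per-label mean/SD/n) and
#'   `comparisons` (tibble: `comparison`, `p_value`, group means).
#' @export
compare_cnr_groups <- function(records) {
  groups <- records |>
    dplyr::filter(!is.na(.data$cnr), !is.na(.data$label)) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(mean_cnr = mean(.data$cnr), sd_cnr = sd(.data$cnr),
                     n = dplyr::n(), .groups = "drop")
  cmp_one <- function(a, b) {
    xa <- records$cnr[records$label == a & !is.na(records$cnr)]
    xb <- records$cnr[records$label == b & !is.na(records$cnr)]
    if (length(xa) < 2L || length(xb) < 2L) {
      warn(sprintf("comparison %s vs %s skipped: fewer than 2 records in a group.", a, b))
      return(NULL)
    }
    tt <- t.test(xa, xb)  # Welch, two-sided
    tibble::tibble(comparison = paste(a, "vs", b),
                   mean_a = mean(xa), mean_b = mean(xb),
                   p_value = tt$p.value)
  }
  list(groups = groups,
       comparisons = dplyr::bind_rows(cmp_one("TP", "FN"), cmp_one("TP", "FP")))
}

#' Summary statistics of a tracking session
#'
#' Mode-time fractions, the number of automatic switches to Calibration
#' mode, and the fraction of those switches that were correct: a switch is
#' correct when the ground-truth balloon lay outside the acquired Runtime
#' stack's slab for every dynamic of the consecutive-miss window that
#' triggered it.
#'
#' @param session A `cathtrack_session`, or its `log` tibble.
#' @param miss_threshold Miss window length; taken from the session config
#'   when a session is supplied.
#' @return One-row tibble: `n_dynamics`, `runtime_fraction`,
#'   `calibration_fraction`, `switch_count`, `correct_switch_fraction`
#'   (`NA` when there are no switches).
#' @export
session_statistics <- function(session, miss_threshold = 5L) {
  log <- if (inherits(session, "cathtrack_session")) session$log else session
  if (inherits(session, "cathtrack_session")) {
    miss_threshold <- session$tracker$miss_threshold
  }
  if (!nrow(log)) abort("empty session log.")
  switches <- which(log$switch_to_calibration)
  correct <- vapply(switches, function(i) {
    win <- seq.int(max(1L, i - miss_threshold + 1L), i)
    all(!log$truth_in_slab[win])
  }, logical(1))
  tibble::tibble(
    n_dynamics = nrow(log),
    runtime_fraction = mean(log$mode == "RUNTIME"),
    calibration_fraction = mean(log$mode == "CALIBRATION"),
    switch_count = length(switches),
    correct_switch_fraction = if (length(switches)) mean(correct) else NA_real_)
}
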