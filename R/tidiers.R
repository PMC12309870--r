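#' Tidy a tracking session
#'
#' @param x A `cathtrack_session`.
#' @param ... Unused.
#' @return The per-dynamic log as a tibble (one row per dynamic).
#' @method tidy cathtrack_session
#' @export
tidy.cathtrack_session <- function(x, ...) x$log

#' One-row summary of a tracking session
#'
#' Mode-time fractions, switch statistics and stack-based detection scores
#' pooled over all dynamics.
#'
#' @param x A `cathtrack_session`.
#' @param ... Unused.
#' @method glance cathtrack_session
#' @export
glance.cathtrack_session <- function(x, ...) {
  st <- session_statistics(x)
  sc <- score_detections(tibble::tibble(label = x$log$stack_label))
  dplyr::bind_cols(st, dplyr::rename_with(sc, ~ paste0("stack_", .x)))
}

#' Per-mode, per-level score table of a session
#'
#' Stack-level labels come from the session's per-dynamic `stack_label`;
#' slice-level labels from the per-dynamic slice label counts.
#'
#' @param session A `cathtrack_session`.
#' @return Tibble of scores with `level` and `mode` columns.
#' @export
session_scores <- function(session) {
  log <- session$log
  stack <- score_detections(
    tibble::tibble(label = log$stack_label, mode = log$mode), .data$mode) |>
    dplyr::mutate(level = "STACK", .before = 1L)
  slice_labels <- log |>
    dplyr::select("mode", "slice_tp", "slice_fp", "slice_fn", "slice_tn") |>
    tidyr::pivot_longer(-"mode", names_to = "label", names_prefix = "slice_",
                        values_to = "n") |>
    dplyr::mutate(label = toupper(.data$label)) |>
    tidyr::uncount(.data$n)
  slice <- score_detections(slice_labels, .data$mode) |>
    dplyr::mutate(level = "SLICE", .before = 1L)
  dplyr::bind_rows(stack, slice)
}

#' Tidy / summarise a trained segmentation model
#'
#' @param x A `unet_model`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch training log; `glance()`: one row with
#'   the final epoch's loss and validation Dice.
#' @method tidy unet_model
#' @export
tidy.unet_model <- function(x, ...) x$log

#' @rdname tidy.unet_model
#' @method glance unet_model
#' @export
glance.unet_model <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), train_loss = last$train_loss,
                 val_dice = last$val_dice,
                 depth = x$depth, base_channels = x$base_channels)
}

#' Plot the through-plane tracking trace of a session
#'
#' Shows the ground-truth balloon offset from the acquired stack centre
#' over dynamics, coloured by mode, with the Runtime slab extent as a
#' band: a working tracker keeps the trace inside the band except during
#' scripted loss windows.
#'
#' @param object A `cathtrack_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cathtrack_session
#' @export
autoplot.cathtrack_session <- function(object, ...) {
  log <- object$log
  half <- object$tracker$runtime$n_slices *
    object$tracker$runtime$thickness_mm / 2
  ggplot2::ggplot(log, ggplot2::aes(x = .data$dynamic,
                                    y = .data$truth_offset_mm)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -half, ymax = half, alpha = 0.15) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$mode,
                                     shape = .data$stack_label)) +
    ggplot2::labs(x = "dynamic", y = "through-plane offset from stack centre (mm)",
                  colour = "mode", shape = "stack label") +
    ggplot2::theme_minimal()
}

#' Histogram of CNR values by detection label
#'
#' Stratified view of contrast-to-noise: one panel per label class
#' (TP/FN/FP), the standard way to show that failures concentrate at low
#' balloon/background CNR.
#'
#' @param records Tibble with `cnr` and `label` columns.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_cnr_histogram <- function(records, bins = 20) {
  ggplot2::ggplot(dplyr::filter(records, !is.na(.data$cnr)),
                  ggplot2::aes(x = .data$cnr)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$label)) +
    ggplot2::labs(x = "balloon/background CNR", y = "count") +
    ggplot2::theme_minimal()
}
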