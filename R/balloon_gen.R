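#' Sample a random artificial balloon shape
#'
#' Draws the parameters of a 2D anisotropic Gaussian balloon the way the
#' semi-artificial training procedure does: each in-plane standard
#' deviation is picked independently and uniformly from \{1.5, 2.5\}
#' pixels, the rotation uniformly on `[0, 360)` degrees, and the amplitude
#' factor uniformly on `[2, 4]` (i.e. 200%-400% of the underlying image
#' signal).
#'
#' @param seed Integer seed; a fixed seed reproduces the draw.
#' @return An object of class `balloon_shape` with fields `sigma_x_px`,
#'   `sigma_y_px`, `rotation_deg`, `amplitude_factor`.
#' @export
sample_balloon_shape <- function(seed = NULL) {
  draw <- function() {
    balloon_shape(
      sigma_x_px = sample(c(1.5, 2.5), 1L),
      sigma_y_px = sample(c(1.5, 2.5), 1L),
      rotation_deg = runif(1L, 0, 360),
      amplitude_factor = runif(1L, 2, 4)
    )
  }
  if (is.null(seed)) draw() else with_seed(as.integer(seed), draw())
}

#' Construct a balloon shape explicitly
#'
#' @param sigma_x_px,sigma_y_px Gaussian SDs along the balloon's own axes,
#'   in pixels (> 0).
#' @param rotation_deg Rotation of the balloon frame, degrees in `[0, 360)`.
#' @param amplitude_factor Peak amplitude as a multiple of the underlying
#'   image signal, in `[2, 4]` when following the sampling procedure;
#'   any positive value is accepted for explicit construction (and 0 as a
#'   degenerate test hook).
#' @return A `balloon_shape`.
#' @export
balloon_shape <- function(sigma_x_px, sigma_y_px, rotation_deg,
                          amplitude_factor) {
  stopifnot_scalar_number(sigma_x_px, "sigma_x_px", 0, strict = TRUE)
  stopifnot_scalar_number(sigma_y_px, "sigma_y_px", 0, strict = TRUE)
  stopifnot_scalar_number(amplitude_factor, "amplitude_factor", 0)
  rotation_deg <- rotation_deg %% 360
  structure(list(sigma_x_px = sigma_x_px, sigma_y_px = sigma_y_px,
                 rotation_deg = rotation_deg,
                 amplitude_factor = amplitude_factor),
            class = "balloon_shape")
}

#' Render an anisotropic 2D Gaussian balloon
#'
#' Evaluates `exp(-q' diag(1/sx^2, 1/sy^2) q / 2)` at every pixel, where
#' `q` is the pixel offset from `center_px` rotated into the balloon frame
#' (by `-rotation_deg`). The returned mask is the half-maximum super-level
#' set (an ellipse), the footprint used as segmentation ground truth.
#'
#' @param shape A [balloon_shape()].
#' @param center_px Balloon centre `(row, col)`, 1-based, may be
#'   fractional; must lie inside the grid.
#' @param grid_shape `c(nrow, ncol)` of the output.
#' @return List with `field` (matrix, peak value 1 at the centre) and
#'   `mask` (logical matrix, `field >= 0.5`).
#' @export
render_balloon <- function(shape, center_px, grid_shape) {
  stopifnot(inherits(shape, "balloon_shape"))
  nr <- grid_shape[1]; nc <- grid_shape[2]
  if (center_px[1] < 1 || center_px[1] > nr ||
      center_px[2] < 1 || center_px[2] > nc) {
    abort("`center_px` must lie inside the grid.")
  }
  dr <- (seq_len(nr) - center_px[1])
  dc <- (seq_len(nc) - center_px[2])
  R <- matrix(dr, nr, nc)
  C <- matrix(dc, nr, nc, byrow = TRUE)
  th <- -shape$rotation_deg * pi / 180
  # rotate offsets into the balloon frame (x = column-, y = row-direction)
  qx <- C * cos(th) - R * sin(th)
  qy <- C * sin(th) + R * cos(th)
  field <- exp(-0.5 * (qx^2 / shape$sigma_x_px^2 + qy^2 / shape$sigma_y_px^2))
  list(field = field, mask = field >= 0.5)
}

#' Inject an artificial balloon into a background image
#'
#' Adds `A * field` to the background, where `field` is the rendered
#' Gaussian and `A = amplitude_factor * local_signal`. The "underlying
#' image signal" is quantified as the mean background intensity in the
#' 5 x 5 neighbourhood of the injection centre; if that local mean is zero
#' (balloon dropped onto empty background), the global mean of positive
#' background pixels is used instead and the sample is flagged.
#'
#' @param background Nonnegative numeric matrix.
#' @param shape A [balloon_shape()].
#' @param center_px Injection centre `(row, col)`, 1-based.
#' @return An object of class `training_sample`: list with `image`, `mask`,
#'   `center_px`, `shape`, `amplitude` (the resolved `A`),
#'   `local_signal_fallback` (logical) and `split` (`NA` until assigned).
#' @examples
#' bg <- matrix(100, 32, 32)
#' s <- inject_balloon(bg, balloon_shape(2.5, 2.5, 0, 3), c(16, 16))
#' max(s$image)  # 100 + 3 * 100 = 400
#' @export
inject_balloon <- function(background, shape, center_px) {
  if (any(background < 0)) abort("`background` must be nonnegative.")
  rb <- render_balloon(shape, center_px, dim(background))
  r0 <- round(center_px[1]); c0 <- round(center_px[2])
  rows <- max(1, r0 - 2):min(nrow(background), r0 + 2)
  cols <- max(1, c0 - 2):min(ncol(background), c0 + 2)
  local <- mean(background[rows, cols])
  fallback <- FALSE
  if (local <= 0) {
    pos <- background[background > 0]
    local <- if (length(pos)) mean(pos) else 1
    fallback <- TRUE
  }
  A <- shape$amplitude_factor * local
  structure(
    list(image = background + A * rb$field,
         mask = if (shape$amplitude_factor > 0) rb$mask else
           matrix(FALSE, nrow(background), ncol(background)),
         center_px = as.numeric(center_px), shape = shape, amplitude = A,
         local_signal_fallback = fallback, split = NA_character_),
    class = "training_sample"
  )
}

#' Generate a semi-artificial training set
#'
#' For each background image, injects balloons with freshly sampled shapes
#' at positions drawn uniformly from a region-of-interest mask (default:
#' the whole image, inset by 3 px so the balloon core stays inside), then
#' appends a configurable fraction of balloon-free negatives and assigns a
#' deterministic TRAIN/VAL split.
#'
#' @param backgrounds List of nonnegative matrices (or a single matrix).
#' @param positions_per_image Balloons injected per background (0 gives
#'   only negatives).
#' @param val_fraction Fraction of samples assigned to the validation
#'   split, in (0, 1). The default 0.31 mirrors a roughly 69/31
#'   train/validation division.
#' @param negative_fraction Balloon-free samples added, as a fraction of
#'   the positive count (default 0.1).
#' @param roi_mask Optional logical matrix restricting injection centres.
#' @param seed Integer seed; the full sample list is reproducible.
#' @return List of `training_sample` objects, each with `split` set to
#'   `"TRAIN"` or `"VAL"`.
#' @export
generate_training_set <- function(backgrounds, positions_per_image,
                                  val_fraction = 0.31,
                                  negative_fraction = 0.1,
                                  roi_mask = NULL, seed = 1L) {
  if (is.matrix(backgrounds)) backgrounds <- list(backgrounds)
  if (!length(backgrounds)) abort("need >= 1 background.")
  if (val_fraction <= 0 || val_fraction >= 1) {
    abort("`val_fraction` must lie in (0, 1).")
  }
  with_seed(as.integer(seed), {
    samples <- list()
    for (bg in backgrounds) {
      nr <- nrow(bg); nc <- ncol(bg)
      ok <- if (is.null(roi_mask)) {
        m <- matrix(FALSE, nr, nc)
        m[4:(nr - 3), 4:(nc - 3)] <- TRUE
        m
      } else roi_mask
      cand <- which(ok)
      if (positions_per_image > 0 && !length(cand)) {
        abort("ROI mask admits no injection centre.")
      }
      for (k in seq_len(positions_per_image)) {
        id <- cand[sample.int(length(cand), 1L)]
        ctr <- c((id - 1L) %% nr + 1L, (id - 1L) %/% nr + 1L)
        samples[[length(samples) + 1L]] <-
          inject_balloon(bg, sample_balloon_shape(), ctr)
      }
    }
    n_pos <- length(samples)
    n_neg <- round(negative_fraction * n_pos)
    if (positions_per_image == 0) n_neg <- max(n_neg, length(backgrounds))
    for (k in seq_len(n_neg)) {
      bg <- backgrounds[[(k - 1L) %% length(backgrounds) + 1L]]
      samples[[length(samples) + 1L]] <- structure(
        list(image = bg, mask = matrix(FALSE, nrow(bg), ncol(bg)),
             center_px = c(NA_real_, NA_real_), shape = NULL,
             amplitude = 0, local_signal_fallback = FALSE,
             split = NA_character_),
        class = "training_sample")
    }
    n <- length(samples)
    n_val <- round(val_fraction * n)
    val_idx <- sample.int(n, n_val)
    for (i in seq_len(n)) {
      samples[[i]]$split <- if (i %in% val_idx) "VAL" else "TRAIN"
    }
    samples
  })
}

#' Write a training set to disk
#'
#' Images and masks as PNG pairs plus a CSV manifest (path, centre, shape
#' parameters, split). Images are normalised to their own max for the
#' 8-bit PNG; the manifest records the scale so intensities can be
#' recovered.
#'
#' @param samples List of `training_sample` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest as a tibble, invisibly; written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_training_set <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::imap(samples, function(s, i) {
    img_path <- file.path(dir, sprintf("sample_%04d.png", i))
    mask_path <- file.path(dir, sprintf("sample_%04d_mask.png", i))
    scale <- max(s$image, 1e-12)
    png::writePNG(s$image / scale, img_path)
    png::writePNG(s$mask * 1, mask_path)
    tibble::tibble(
      image = basename(img_path), mask = basename(mask_path),
      intensity_scale = scale,
      center_row = s$center_px[1], center_col = s$center_px[2],
      sigma_x_px = if (is.null(s$shape)) NA_real_ else s$shape$sigma_x_px,
      sigma_y_px = if (is.null(s$shape)) NA_real_ else s$shape$sigma_y_px,
      rotation_deg = if (is.null(s$shape)) NA_real_ else s$shape$rotation_deg,
      amplitude_factor = if (is.null(s$shape)) NA_real_ else
        s$shape$amplitude_factor,
      split = s$split)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a grayscale background image
#'
#' Accepts PNG (first channel of RGB(A)) or NIfTI (a single slice index of
#' a volume). Values are returned as a nonnegative numeric matrix.
#'
#' @param path `.png`, `.nii` or `.nii.gz` file.
#' @param slice For NIfTI volumes, which third-dimension slice to extract.
#' @export
read_background_image <- function(path, slice = 1L) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    im <- png::readPNG(path)
    if (length(dim(im)) == 3L) im <- im[, , 1L]
    return(im)
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) == 3L) a <- a[, , slice]
    return(a)
  }
  abort("unsupported background format (use PNG or NIfTI).")
}
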