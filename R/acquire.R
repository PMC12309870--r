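#' Through-plane partial-volume weight
#'
#' Fraction of the balloon's through-plane extent `[offset - r, offset + r]`
#' that overlaps the slab `[-T/2, +T/2]`, normalised by the full extent
#' `2r`. This is the signal-dilution factor applied to a small bright
#' balloon imaged by a thick slab: 1 when the balloon is fully contained,
#' 0 when it is disjoint from the slab, and symmetric in the sign of the
#' offset. Summed over the slices of a contiguous stack that fully covers
#' the balloon, the weights add to exactly 1 (the slabs partition the
#' through-plane axis), which is what makes the balloon appear, diluted,
#' in adjacent slices.
#'
#' @param balloon_offset_mm Signed through-plane distance from the slice
#'   centre to the balloon centre (mm).
#' @param radius_mm Balloon radius (> 0), mm.
#' @param thickness_mm Slab thickness (> 0), mm.
#' @return Weight in `[0, 1]`. Vectorised over `balloon_offset_mm`.
#' @examples
#' partial_volume_weight(0, radius_mm = 4, thickness_mm = 10)   # 1
#' partial_volume_weight(5, radius_mm = 2.5, thickness_mm = 10) # 0.5
#' @export
partial_volume_weight <- function(balloon_offset_mm, radius_mm, thickness_mm) {
  stopifnot_scalar_number(radius_mm, "radius_mm", 0, strict = TRUE)
  stopifnot_scalar_number(thickness_mm, "thickness_mm", 0, strict = TRUE)
  lo <- pmax(balloon_offset_mm - radius_mm, -thickness_mm / 2)
  hi <- pmin(balloon_offset_mm + radius_mm, thickness_mm / 2)
  pmax(hi - lo, 0) / (2 * radius_mm)
}

# In-plane Gaussian sigma for a balloon of radius r: chosen so the
# half-maximum contour of the footprint sits at the balloon radius
# (r = sigma * sqrt(2 ln 2)).
balloon_sigma_mm <- function(radius_mm) radius_mm / sqrt(2 * log(2))

# In-plane pixel-centre offsets (mm) from the slice centre along the u and
# v axes. 0-based pixel (row, col): col indexes u, row indexes v; the image
# centre coincides with the slice centre.
pixel_offsets <- function(prescription) {
  nu <- prescription$matrix[1]; nv <- prescription$matrix[2]
  list(
    u = ((seq_len(nu) - 1) - (nu - 1) / 2) * prescription$fov_mm[1] / nu,
    v = ((seq_len(nv) - 1) - (nv - 1) / 2) * prescription$fov_mm[2] / nv
  )
}

# Balloon's in-plane squared distance field (mm^2) on the slice pixel grid:
# matrix [row = v, col = u].
balloon_dist2 <- function(balloon, prescription, slice_index) {
  sc <- slice_centers(prescription)[slice_index + 1L, ]
  q <- balloon$position_mm - sc
  off <- pixel_offsets(prescription)
  du <- off$u - sum(q * prescription$in_plane_axes[, 1])
  dv <- off$v - sum(q * prescription$in_plane_axes[, 2])
  outer(dv^2, du^2, "+")
}

#' Simulate acquisition of one 2D slice
#'
#' Phenomenological single-shot image formation: the tissue term is the
#' slab-averaged phantom intensity (mean of 5 equispaced sample planes
#' through the slab, trilinear interpolation) attenuated by
#' `cos(prep_angle_deg)` — a 90 degree nonselective saturation prepulse
#' nulls tissue entirely, a 50 degree partial-saturation (pSAT) prepulse
#' leaves `cos(50)` of it. The balloon term adds the balloon's intrinsic
#' brightness, *not* attenuated by the prepulse (short-T1 gadolinium
#' filling recovers immediately), scaled by the through-plane
#' [partial_volume_weight()] and an in-plane Gaussian footprint whose
#' half-maximum contour matches the balloon radius. Zero-mean Gaussian
#' noise is added and negative pixels are clipped to 0 (magnitude-image
#' approximation).
#'
#' @param volume A [voxel_volume()] phantom.
#' @param balloon A [balloon_truth()], or `NULL` for no balloon.
#' @param prescription A [slice_prescription()].
#' @param slice_index 0-based slice within the stack.
#' @param prep_angle_deg Preparation pulse angle in degrees, in `[0, 90]`.
#' @param noise_sd Additive Gaussian noise SD (image units).
#' @param seed Experiment seed; the noise stream is derived from
#'   `(seed, dynamic_index, slice_index)` so acquisitions are reproducible
#'   independent of order.
#' @param dynamic_index 0-based dynamic, used only for noise seeding.
#' @param n_slab_samples Number of equispaced in-slab sample planes for the
#'   tissue term (default 5).
#' @return An object of class `slice_image` with fields `pixels`
#'   (matrix `[v, u]`), `prescription`, `slice_index`, `prep_angle_deg`,
#'   `noise_sd`.
#' @export
sample_slice <- function(volume, balloon, prescription, slice_index,
                         prep_angle_deg, noise_sd = 0, seed = 1L,
                         dynamic_index = 0L, n_slab_samples = 5L) {
  stopifnot(inherits(prescription, "slice_prescription"))
  if (slice_index < 0L || slice_index >= prescription$n_slices) {
    abort("`slice_index` out of range.")
  }
  if (prep_angle_deg < 0 || prep_angle_deg > 90) {
    abort("`prep_angle_deg` must lie in [0, 90].")
  }
  nu <- prescription$matrix[1]; nv <- prescription$matrix[2]
  sc <- slice_centers(prescription)[slice_index + 1L, ]
  img <- matrix(0, nrow = nv, ncol = nu)

  ca <- cos(prep_angle_deg * pi / 180)
  if (abs(ca) > 1e-12 && !is.null(volume)) {
    off <- pixel_offsets(prescription)
    u <- prescription$in_plane_axes[, 1]; v <- prescription$in_plane_axes[, 2]
    # pixel grid world coordinates (rows vary fastest: v axis)
    base <- cbind(
      sc[1] + rep(off$v, times = nu) * v[1] + rep(off$u, each = nv) * u[1],
      sc[2] + rep(off$v, times = nu) * v[2] + rep(off$u, each = nv) * u[2],
      sc[3] + rep(off$v, times = nu) * v[3] + rep(off$u, each = nv) * u[3]
    )
    K <- as.integer(n_slab_samples)
    tk <- (-prescription$thickness_mm / 2 +
             (seq_len(K) - 0.5) * prescription$thickness_mm / K)
    acc <- numeric(nv * nu)
    for (t in tk) {
      pts <- base
      pts[, 1] <- pts[, 1] + t * prescription$normal[1]
      pts[, 2] <- pts[, 2] + t * prescription$normal[2]
      pts[, 3] <- pts[, 3] + t * prescription$normal[3]
      acc <- acc + interp_trilinear(volume, pts)
    }
    img <- img + ca * matrix(acc / K, nrow = nv, ncol = nu)
  }

  if (!is.null(balloon)) {
    w <- partial_volume_weight(
      through_plane_offset(prescription, balloon$position_mm) -
        through_plane_offset(prescription, sc),
      balloon$radius_mm, prescription$thickness_mm)
    if (w > 0) {
      s2 <- balloon_sigma_mm(balloon$radius_mm)^2
      img <- img + balloon$brightness * w *
        exp(-balloon_dist2(balloon, prescription, slice_index) / (2 * s2))
    }
  }

  if (noise_sd > 0) {
    n <- with_seed(substream_seed(seed, dynamic_index, slice_index), {
      rnorm(nv * nu, 0, noise_sd)
    })
    img <- img + matrix(n, nrow = nv, ncol = nu)
  }
  img[img < 0] <- 0

  structure(
    list(pixels = img, prescription = prescription,
         slice_index = as.integer(slice_index),
         prep_angle_deg = prep_angle_deg, noise_sd = noise_sd),
    class = "slice_image"
  )
}

#' Ground-truth balloon mask on a slice
#'
#' The reference footprint used for evaluation: empty when the balloon does
#' not overlap the slab (partial-volume weight 0), otherwise the in-plane
#' half-maximum contour of the balloon's Gaussian footprint (an ellipse of
#' radius equal to the balloon radius). Note the mask extent does not shrink
#' with partial-volume dilution — the balloon is "present" in every slab it
#' overlaps, however faintly, mirroring how a human annotator would mark it.
#'
#' @inheritParams sample_slice
#' @return Logical matrix of the slice's shape.
#' @export
truth_slice_mask <- function(balloon, prescription, slice_index) {
  sc <- slice_centers(prescription)[slice_index + 1L, ]
  w <- partial_volume_weight(
    through_plane_offset(prescription, balloon$position_mm) -
      through_plane_offset(prescription, sc),
    balloon$radius_mm, prescription$thickness_mm)
  if (w <= 0) {
    return(matrix(FALSE, prescription$matrix[2], prescription$matrix[1]))
  }
  s2 <- balloon_sigma_mm(balloon$radius_mm)^2
  exp(-balloon_dist2(balloon, prescription, slice_index) / (2 * s2)) >= 0.5
}

#' Acquire a full stack of slices for one dynamic
#'
#' One [sample_slice()] per slice of the prescription. The preparation
#' angle follows the mode — 90 degrees (nonselective saturation) for
#' `CALIBRATION`, 50 degrees (pSAT) for `RUNTIME` — unless overridden.
#' Each slice draws its noise from an independent substream derived from
#' `(seed, dynamic_index, slice_index)`.
#'
#' @inheritParams sample_slice
#' @param mode `"CALIBRATION"` or `"RUNTIME"`.
#' @param prep_angle_deg Optional override of the mode's prep angle.
#' @return An object of class `stack_images`: list with `slices` (list of
#'   `slice_image`), `mode`, `dynamic_index`, `prescription`,
#'   `prep_angle_deg`.
#' @export
acquire_stack <- function(volume, balloon, prescription, mode,
                          dynamic_index = 0L, noise_sd = 0, seed = 1L,
                          prep_angle_deg = NULL, n_slab_samples = 5L) {
  mode <- match.arg(mode, c("CALIBRATION", "RUNTIME"))
  if (is.null(prep_angle_deg)) {
    prep_angle_deg <- if (mode == "CALIBRATION") 90 else 50
  }
  slices <- lapply(seq_len(prescription$n_slices) - 1L, function(i) {
    sample_slice(volume, balloon, prescription, i, prep_angle_deg,
                 noise_sd = noise_sd, seed = seed,
                 dynamic_index = dynamic_index,
                 n_slab_samples = n_slab_samples)
  })
  structure(
    list(slices = slices, mode = mode,
         dynamic_index = as.integer(dynamic_index),
         prescription = prescription, prep_angle_deg = prep_angle_deg),
    class = "stack_images"
  )
}

#' Write a stack as a 3D NIfTI image
#'
#' Slices become the third array dimension; in-plane pixel pitch and slice
#' thickness go into the pixdim.
#'
#' @param stack A `stack_images` object.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @export
write_stack_nifti <- function(stack, path) {
  p <- stack$prescription
  arr <- array(0, dim = c(p$matrix[2], p$matrix[1], p$n_slices))
  for (i in seq_along(stack$slices)) arr[, , i] <- stack$slices[[i]]$pixels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(p$fov_mm[2] / p$matrix[2],
                           p$fov_mm[1] / p$matrix[1], p$thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a slice (or any image matrix) as a windowed 8-bit PNG
#'
#' For documentation/reporting only; intensities are min-max windowed.
#'
#' @param image A `slice_image` or a numeric matrix.
#' @param path Output `.png` path.
#' @param window Optional `c(low, high)` display window.
#' @export
write_image_png <- function(image, path, window = NULL) {
  px <- if (inherits(image, "slice_image")) image$pixels else image
  if (is.null(window)) window <- range(px)
  if (diff(window) <= 0) window <- window + c(0, 1)
  z <- pmin(pmax((px - window[1]) / diff(window), 0), 1)
  png::writePNG(z, path)
  invisible(path)
}
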