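#' Slice-stack prescription
#'
#' A prescription describes one contiguous stack of 2D slices in world
#' (scanner) coordinates: the stack centre, the through-plane unit normal,
#' two orthonormal in-plane axes, the slice count and thickness, and the
#' in-plane field of view and acquisition matrix. Slice `i` (0-based) is
#' centred at `center_mm + (i - (n_slices - 1)/2) * thickness_mm * normal`,
#' so neighbouring slice centres are exactly one slice thickness apart
#' (contiguous slices, no gap and no overlap).
#'
#' Pixel `(row, col)` (0-based) of a slice maps to the world point
#' `slice_center + (col - (ncol-1)/2) * pitch_u * u + (row - (nrow-1)/2) *
#' pitch_v * v` where `u`, `v` are the in-plane axes and the pitches are
#' `fov_mm / matrix`. The image centre therefore coincides with the slice
#' centre.
#'
#' @param center_mm World coordinate (mm) of the stack centre, length 3.
#' @param normal Through-plane direction; normalised internally.
#' @param n_slices Number of contiguous slices (positive integer).
#' @param thickness_mm Slice thickness in mm (> 0).
#' @param fov_mm In-plane field of view, length 2 (`c(fov_u, fov_v)`), mm.
#' @param matrix In-plane matrix size, length 2 (`c(ncol, nrow)` along the
#'   `u` and `v` axes), each >= 8.
#' @param in_plane_axes Optional 3 x 2 matrix with orthonormal in-plane axes
#'   `u`, `v` as columns, both orthogonal to `normal`. Defaults to an
#'   arbitrary right-handed completion of `normal`.
#' @return An object of class `slice_prescription`.
#' @examples
#' p <- slice_prescription(c(0, 0, 0), normal = c(0, 1, 0),
#'                         n_slices = 3, thickness_mm = 10,
#'                         fov_mm = c(300, 300), matrix = c(128, 128))
#' slice_centers(p)
#' @export
slice_prescription <- function(center_mm, normal, n_slices, thickness_mm,
                               fov_mm, matrix, in_plane_axes = NULL) {
  center_mm <- as_point3(center_mm, "center_mm")
  normal <- unit3(normal, "normal")
  if (!is.numeric(n_slices) || length(n_slices) != 1L || n_slices < 1 ||
      n_slices != round(n_slices)) {
    abort("`n_slices` must be a positive integer.")
  }
  stopifnot_scalar_number(thickness_mm, "thickness_mm", 0, strict = TRUE)
  fov_mm <- as.numeric(fov_mm)
  if (length(fov_mm) == 1L) fov_mm <- rep(fov_mm, 2L)
  if (length(fov_mm) != 2L || any(fov_mm <= 0)) {
    abort("`fov_mm` must be two positive extents.")
  }
  matrix <- as.integer(matrix)
  if (length(matrix) == 1L) matrix <- rep(matrix, 2L)
  if (length(matrix) != 2L || any(matrix < 8L)) {
    abort("`matrix` must be two integers >= 8.")
  }
  if (is.null(in_plane_axes)) {
    in_plane_axes <- complete_frame(normal)
  } else {
    in_plane_axes <- base::matrix(as.numeric(in_plane_axes), nrow = 3L)
    if (ncol(in_plane_axes) != 2L) abort("`in_plane_axes` must be 3 x 2.")
    ips <- crossprod(cbind(normal, in_plane_axes))
    if (max(abs(ips - diag(3))) > 1e-8) {
      abort("`in_plane_axes` must be unit length and orthogonal to `normal` and to each other.")
    }
  }
  structure(
    list(center_mm = center_mm, normal = normal,
         in_plane_axes = in_plane_axes,
         n_slices = as.integer(n_slices), thickness_mm = thickness_mm,
         fov_mm = fov_mm, matrix = matrix),
    class = "slice_prescription"
  )
}

# Right-handed orthonormal completion of a unit normal: pick the world axis
# least aligned with n, project it out, then cross for the second axis.
complete_frame <- function(n) {
  ref <- diag(3)[, which.min(abs(n))]
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  cbind(u, v)
}

#' Slice centres of a prescription
#'
#' @param prescription A [slice_prescription()].
#' @return An `n_slices` x 3 matrix of world coordinates (mm), row `i`
#'   holding the centre of slice `i - 1`.
#' @export
slice_centers <- function(prescription) {
  stopifnot(inherits(prescription, "slice_prescription"))
  i <- seq_len(prescription$n_slices) - 1
  off <- (i - (prescription$n_slices - 1) / 2) * prescription$thickness_mm
  t(prescription$center_mm + outer(prescription$normal, off))
}

#' Through-plane offset of a world point from a prescription centre
#'
#' @param prescription A [slice_prescription()].
#' @param point_mm World coordinate, length 3.
#' @return Signed distance (mm) along the stack normal from the stack centre.
#' @export
through_plane_offset <- function(prescription, point_mm) {
  sum((as_point3(point_mm) - prescription$center_mm) * prescription$normal)
}

#' Does a world point lie within a stack's slab?
#'
#' The slab is the through-plane extent covered by the contiguous slices:
#' `n_slices * thickness_mm` centred on the stack centre.
#'
#' @inheritParams through_plane_offset
#' @return `TRUE` if the point's through-plane offset is within the slab.
#' @export
point_in_slab <- function(prescription, point_mm) {
  abs(through_plane_offset(prescription, point_mm)) <=
    prescription$n_slices * prescription$thickness_mm / 2
}

#' Translate a prescription to a new centre
#'
#' Keeps orientation, slice count, thickness, FOV and matrix; replaces the
#' stack centre. Used when the Runtime stack is recentred on a detected
#' balloon position.
#'
#' @inheritParams slice_centers
#' @param center_mm New world centre (mm).
#' @export
recenter_prescription <- function(prescription, center_mm) {
  prescription$center_mm <- as_point3(center_mm, "center_mm")
  prescription
}

#' @export
print.slice_prescription <- function(x, ...) {
  cat(sprintf(
    "<slice_prescription> %d slice(s) x %.1f mm, FOV %.0f x %.0f mm, matrix %d x %d\n",
    x$n_slices, x$thickness_mm, x$fov_mm[1], x$fov_mm[2],
    x$matrix[1], x$matrix[2]))
  cat(sprintf("  center (%.1f, %.1f, %.1f) mm, normal (%.2f, %.2f, %.2f)\n",
              x$center_mm[1], x$center_mm[2], x$center_mm[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}
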