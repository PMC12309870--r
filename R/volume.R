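#' Voxel volume (digital phantom)
#'
#' A 3D scalar intensity grid with physical voxel spacing and a world origin:
#' the world position of the centre of voxel `(0, 0, 0)` (0-based indices).
#' Stands in for the imaged object — here typically a water-filled container
#' holding a printed heart phantom with tubular lumina.
#'
#' @param intensities 3D numeric array, all values finite and >= 0, at least
#'   2 voxels per axis.
#' @param spacing_mm Per-axis voxel size in mm (all > 0).
#' @param origin_mm World coordinate of the centre of voxel (0,0,0).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3D array.")
  }
  if (any(dim(intensities) < 2L)) abort("grid needs >= 2 voxels per axis.")
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    abort("`intensities` must be finite and >= 0.")
  }
  spacing_mm <- as_point3(spacing_mm, "spacing_mm")
  if (any(spacing_mm <= 0)) abort("all `spacing_mm` components must be > 0.")
  structure(
    list(intensities = intensities, spacing_mm = spacing_mm,
         origin_mm = as_point3(origin_mm, "origin_mm")),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  invisible(x)
}

# Trilinear interpolation of a voxel_volume at world points (n x 3 matrix).
# Points outside the grid return `outside` (default 0). Vectorised.
interp_trilinear <- function(volume, points_mm, outside = 0) {
  v <- volume$intensities
  d <- dim(v)
  # continuous 0-based voxel coordinates
  g <- sweep(sweep(points_mm, 2L, volume$origin_mm, "-"), 2L,
             volume$spacing_mm, "/")
  i0 <- floor(g)
  f <- g - i0
  out <- numeric(nrow(g))
  inside <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
    g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
    g[, 3] >= 0 & g[, 3] <= d[3] - 1
  out[!inside] <- outside
  if (any(inside)) {
    i0i <- pmin(pmax(i0[inside, , drop = FALSE], 0), rep(d - 2, each = sum(inside)))
    fi <- g[inside, , drop = FALSE] - i0i
    x0 <- i0i[, 1]; y0 <- i0i[, 2]; z0 <- i0i[, 3]
    fx <- fi[, 1]; fy <- fi[, 2]; fz <- fi[, 3]
    at <- function(dx, dy, dz) {
      v[cbind(x0 + dx + 1, y0 + dy + 1, z0 + dz + 1)]
    }
    c00 <- at(0, 0, 0) * (1 - fx) + at(1, 0, 0) * fx
    c10 <- at(0, 1, 0) * (1 - fx) + at(1, 1, 0) * fx
    c01 <- at(0, 0, 1) * (1 - fx) + at(1, 0, 1) * fx
    c11 <- at(0, 1, 1) * (1 - fx) + at(1, 1, 1) * fx
    c0 <- c00 * (1 - fy) + c10 * fy
    c1 <- c01 * (1 - fy) + c11 * fy
    out[inside] <- c0 * (1 - fz) + c1 * fz
  }
  out
}

#' Build a digital phantom volume
#'
#' Constructs the simulator's stand-in for a 3D-printed heart phantom in a
#' water bath: a uniform "body" block at `tissue_level`, optionally carrying
#' brighter (or darker) vessel-like primitives, surrounded by zero signal
#' (air). Primitives may overlap; the maximum intensity wins. An optional
#' multiplicative speckle texture (log-normal-ish, seeded) roughens the
#' body so images are not perfectly flat.
#'
#' @param shape Voxel counts per axis, each >= 16.
#' @param vessel_spec List of primitives. Each is a list with `type`
#'   (`"tube"` or `"sphere"`), an `intensity`, and geometry: tubes take
#'   `from`, `to` (world mm endpoints) and `radius_mm`; spheres take
#'   `center` and `radius_mm`.
#' @param tissue_level Background body intensity (> 0), arbitrary units.
#' @param spacing_mm Voxel size, mm (scalar or length 3).
#' @param body_margin_mm Margin of zero-signal air between the body block
#'   and the grid boundary, mm.
#' @param texture_sd Relative SD of the multiplicative body texture
#'   (0 disables; default 0).
#' @param seed Integer seed for the texture; the result is deterministic
#'   for a fixed seed.
#' @return A [voxel_volume()] whose origin places the volume centre at the
#'   world origin.
#' @examples
#' vol <- build_phantom(c(32, 32, 32), tissue_level = 100)
#' range(vol$intensities)
#' @export
build_phantom <- function(shape, vessel_spec = list(), tissue_level = 100,
                          spacing_mm = 2, body_margin_mm = 4,
                          texture_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(shape) != 3L || any(shape < 16L)) {
    abort("`shape` must give >= 16 voxels per axis.")
  }
  stopifnot_scalar_number(tissue_level, "tissue_level", 0, strict = TRUE)
  spacing_mm <- if (length(spacing_mm) == 1L) rep(spacing_mm, 3L) else as_point3(spacing_mm)
  extent <- shape * spacing_mm
  origin <- -(extent - spacing_mm) / 2  # volume centred on world origin

  ax <- lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing_mm[a])
  # world coordinate arrays, recycled along the grid
  X <- array(ax[[1]], dim = shape)
  Y <- array(rep(ax[[2]], each = shape[1]), dim = shape)
  Z <- array(rep(ax[[3]], each = shape[1] * shape[2]), dim = shape)

  body <- X >= origin[1] + body_margin_mm & X <= -origin[1] - body_margin_mm &
    Y >= origin[2] + body_margin_mm & Y <= -origin[2] - body_margin_mm &
    Z >= origin[3] + body_margin_mm & Z <= -origin[3] - body_margin_mm

  vox <- array(0, dim = shape)
  vox[body] <- tissue_level
  if (texture_sd > 0) {
    tex <- with_seed(as.integer(seed), {
      array(exp(rnorm(prod(shape), 0, texture_sd)), dim = shape)
    })
    vox[body] <- vox[body] * tex[body]
  }

  for (prim in vessel_spec) {
    if (is.null(prim$type)) abort("each vessel primitive needs a `type`.")
    lum <- if (is.null(prim$intensity)) 2 * tissue_level else prim$intensity
    inside <- switch(
      prim$type,
      tube = {
        a <- as_point3(prim$from, "from"); b <- as_point3(prim$to, "to")
        ab <- b - a
        len2 <- sum(ab^2)
        if (len2 < 1e-12) abort("tube endpoints coincide.")
        t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2] + (Z - a[3]) * ab[3]) / len2
        t <- pmin(pmax(t, 0), 1)
        d2 <- (X - (a[1] + t * ab[1]))^2 + (Y - (a[2] + t * ab[2]))^2 +
          (Z - (a[3] + t * ab[3]))^2
        d2 <= prim$radius_mm^2
      },
      sphere = {
        ctr <- as_point3(prim$center, "center")
        (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= prim$radius_mm^2
      },
      abort(sprintf("unknown primitive type '%s'.", prim$type))
    )
    sel <- inside & body
    vox[sel] <- pmax(vox[sel], lum)  # overlap: max rule
  }

  voxel_volume(vox, spacing_mm, origin)
}

#' Read / write a voxel volume as NIfTI-1
#'
#' Spacing is carried in the NIfTI pixdim; the world origin is stored in the
#' sform translation.
#'
#' @param volume A [voxel_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_volume_nifti()` returns a [voxel_volume()].
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$spacing_mm
  xf <- diag(c(volume$spacing_mm, 1))
  xf[1:3, 4] <- volume$origin_mm
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing_mm = RNifti::pixdim(img)[1:3],
               origin_mm = xf[1:3, 4])
}
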