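#' CT volume container
#'
#' A 3D scalar intensity grid with physical spacing and origin under the
#' project axis convention: array axes 1, 2, 3 correspond to patient axes
#' (x, z, y); see \link{contourcast-package}. Intensities are HU-like.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, mm per voxel along (x, z, y); all > 0.
#' @param origin numeric length-3, mm coordinate of the centre of voxel
#'   `[1, 1, 1]`, in (x, z, y) order.
#' @return An object of class `ct_volume`: a list with `data`, `spacing`,
#'   `origin` and an `axes` orientation tag.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(!is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, spacing = spacing, origin = origin,
                 axes = cc_axes()),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels; spacing (x,z,y) = ",
      paste(signif(x$spacing, 6), collapse = ", "), " mm; origin = ",
      paste(signif(x$origin, 6), collapse = ", "), " mm\n", sep = "")
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

#' Physical coordinates of voxel centres along one axis
#' @param vol a `ct_volume`.
#' @param axis integer 1 (x), 2 (z) or 3 (y).
#' @return Numeric vector of mm coordinates.
#' @export
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

#' Physical bounding box of a volume's voxel centres
#' @param vol a `ct_volume`.
#' @return 2 x 3 matrix, rows = (lower, upper) mm per axis.
#' @export
volume_bounds <- function(vol) {
  lo <- vol$origin
  hi <- vol$origin + (dim(vol$data) - 1) * vol$spacing
  rbind(lower = lo, upper = hi)
}

# world mm -> continuous 1-based array index
world_to_index <- function(vol, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

index_to_world <- function(vol, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Trilinear interpolation of a volume at physical points
#'
#' @param vol a `ct_volume`.
#' @param pts n x 3 matrix of (x, z, y) mm points.
#' @param outside value returned for points outside the voxel-centre hull
#'   (default `NA`, so callers can exclude them from similarity measures).
#' @return Numeric vector of length n.
#' @export
interp_volume <- function(vol, pts, outside = NA_real_) {
  idx <- world_to_index(vol, pts)
  d <- dim(vol$data)
  ix <- idx[, 1]; iz <- idx[, 2]; iy <- idx[, 3]
  # tolerate roundoff at the domain boundary, then clamp onto it
  tol <- 1e-9
  ok <- ix >= 1 - tol & ix <= d[1] + tol & iz >= 1 - tol & iz <= d[2] + tol &
    iy >= 1 - tol & iy <= d[3] + tol
  ix <- pmin(pmax(ix, 1), d[1])
  iz <- pmin(pmax(iz, 1), d[2])
  iy <- pmin(pmax(iy, 1), d[3])
  out <- rep(outside, nrow(idx))
  if (!any(ok)) return(out)
  ix <- ix[ok]; iz <- iz[ok]; iy <- iy[ok]
  i0 <- pmin(floor(ix), d[1] - 1); fx <- ix - i0
  j0 <- pmin(floor(iz), d[2] - 1); fz <- iz - j0
  k0 <- pmin(floor(iy), d[3] - 1); fy <- iy - k0
  if (d[1] < 2 || d[2] < 2 || d[3] < 2) stop("volume too small to interpolate")
  a <- vol$data
  g <- function(di, dj, dk) a[cbind(i0 + di, j0 + dj, k0 + dk)]
  v <-
    g(0,0,0) * (1-fx)*(1-fz)*(1-fy) + g(1,0,0) * fx*(1-fz)*(1-fy) +
    g(0,1,0) * (1-fx)*fz*(1-fy)     + g(1,1,0) * fx*fz*(1-fy) +
    g(0,0,1) * (1-fx)*(1-fz)*fy     + g(1,0,1) * fx*(1-fz)*fy +
    g(0,1,1) * (1-fx)*fz*fy         + g(1,1,1) * fx*fz*fy
  out[ok] <- v
  out
}

# separable 1D convolution along array axis 1 with edge replication
conv_axis1 <- function(a, kernel) {
  d <- dim(a); hw <- (length(kernel) - 1L) %/% 2L
  m <- matrix(a, nrow = d[1])
  pad_top <- m[rep(1L, hw), , drop = FALSE]
  pad_bot <- m[rep(d[1], hw), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  f <- stats::filter(mp, kernel, sides = 2)
  array(as.numeric(f[(hw + 1L):(hw + d[1]), , drop = FALSE]), dim = d)
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian smoothing of a volume
#' @param vol a `ct_volume`.
#' @param sigma_vox per-axis Gaussian sigma in voxels (length 1 or 3).
#' @return Smoothed `ct_volume`.
#' @export
smooth_volume <- function(vol, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  a <- vol$data
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0 || dim(a)[ax] < 4) next
    k <- gauss_kernel(sigma_vox[ax])
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    ap <- aperm(a, perm)
    ap <- conv_axis1(ap, k)
    a <- aperm(ap, order(perm))
  }
  ct_volume(a, vol$spacing, vol$origin)
}

#' Downsample a volume by an integer factor per axis
#'
#' Gaussian pre-smoothing (sigma = 0.5 * factor voxels) then decimation.
#' Axes with fewer than 8 samples are left at full resolution so the 5 mm
#' slice axis is not collapsed on coarse pyramid levels.
#'
#' @param vol a `ct_volume`.
#' @param factor integer decimation factor (length 1 or 3).
#' @return Downsampled `ct_volume` (spacing scaled accordingly).
#' @export
downsample_volume <- function(vol, factor = 2L) {
  factor <- rep(as.integer(factor), length.out = 3)
  d <- dim(vol$data)
  factor[d < 8L] <- 1L
  if (all(factor == 1L)) return(vol)
  sm <- smooth_volume(vol, ifelse(factor > 1L, 0.5 * factor, 0))
  ii <- lapply(1:3, function(ax) seq(1L, d[ax], by = factor[ax]))
  ct_volume(sm$data[ii[[1]], ii[[2]], ii[[3]], drop = FALSE],
            vol$spacing * factor, vol$origin)
}

#' Read a CT volume from NIfTI
#'
#' The file's voxel axes are interpreted under the project convention
#' (array axes = patient x, z, y); the qform/sform must be axis-aligned with
#' positive scales, as written by \code{\link{write_volume}}. Spacing and
#' origin round-trip to well below 1e-3 mm.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @return A `ct_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  m <- unclass(xf)[1:3, 1:3]
  if (max(abs(m - diag(diag(m)))) > 1e-4 || any(diag(m) <= 0))
    stop("unsupported NIfTI orientation: expected axis-aligned positive-scale ",
         "transform under the (x, z, y) project convention")
  a <- array(as.numeric(img), dim = dim(img))
  ct_volume(a, spacing = diag(m), origin = unclass(xf)[1:3, 4])
}

#' Write a CT volume to NIfTI
#' @param vol a `ct_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  xf <- diag(c(vol$spacing, 1))
  xf[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
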