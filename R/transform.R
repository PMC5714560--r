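#' Affine spatial transform
#'
#' 12-parameter affine map in patient mm coordinates:
#' `T(x) = M (x - center) + center + translation`, with linear part
#' `M = R %*% Sh %*% diag(scale)` — rotations applied last, then shear, then
#' anisotropic scaling. Rotations are about the (x, z, y) component axes, in
#' degrees, composed as `R = R_y R_z R_x`. Shear is a unit upper-triangular
#' matrix with off-diagonal entries `(sh_xz, sh_xy, sh_zy)`.
#'
#' @param translation length-3 mm.
#' @param rotation_deg length-3 degrees about the x, z, y axes.
#' @param scale length-3 anisotropic scale factors (all > 0).
#' @param shear length-3 shear coefficients.
#' @param center length-3 mm fixed centre of rotation/scaling.
#' @return An object of class `cc_affine` with the 3x3 matrix `A` and offset
#'   `b` such that `T(x) = A x + b`, plus the generating parameters.
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation_deg = c(0, 0, 0),
                             scale = c(1, 1, 1),
                             shear = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation_deg) == 3,
            length(scale) == 3, length(shear) == 3, length(center) == 3)
  if (any(scale <= 0)) stop("scale factors must be strictly positive")
  r <- rotation_deg * pi / 180
  rot1 <- function(a, i, j) {          # rotation in the (i, j) coordinate plane
    m <- diag(3)
    m[i, i] <- cos(a); m[j, j] <- cos(a)
    m[i, j] <- -sin(a); m[j, i] <- sin(a)
    m
  }
  R <- rot1(r[3], 1, 2) %*% rot1(r[2], 3, 1) %*% rot1(r[1], 2, 3)
  Sh <- diag(3)
  Sh[1, 2] <- shear[1]; Sh[1, 3] <- shear[2]; Sh[2, 3] <- shear[3]
  M <- R %*% Sh %*% diag(scale)
  if (det(M) <= 0) stop("affine transform is not orientation-preserving")
  A <- M
  b <- as.numeric(center + translation - M %*% center)
  structure(list(A = A, b = b,
                 params = list(translation = translation,
                               rotation_deg = rotation_deg,
                               scale = scale, shear = shear, center = center)),
            class = "cc_affine")
}

affine_from_matrix <- function(A, b) {
  if (det(A) <= 0) stop("affine matrix must have positive determinant")
  structure(list(A = A, b = as.numeric(b), params = NULL), class = "cc_affine")
}

#' @export
print.cc_affine <- function(x, ...) {
  cat("<cc_affine> det(A) =", signif(det(x$A), 6), "\n")
  invisible(x)
}

apply_affine <- function(t, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(t$A), 2, t$b, "+")
}

invert_affine <- function(t) {
  Ai <- solve(t$A)
  affine_from_matrix(Ai, -Ai %*% t$b)
}

# ---------------------------------------------------------------------------
# cubic B-spline displacement field on a regular control grid

bspline_w <- function(t) {
  # the four uniform cubic B-spline weights for fractional offset t in [0,1)
  t2 <- t * t; t3 <- t2 * t
  cbind((1 - 3 * t + 3 * t2 - t3) / 6,
        (4 - 6 * t2 + 3 * t3) / 6,
        (1 + 3 * t + 3 * t2 - 3 * t3) / 6,
        t3 / 6)
}

#' Cubic B-spline displacement field on a regular control grid
#'
#' Displacement vectors (mm) attached to a regular lattice of control points;
#' the dense field is the tensor-product cubic B-spline interpolation of the
#' lattice. Because the cubic B-spline weights are non-negative and sum to
#' one, the dense displacement is bounded componentwise by the control
#' displacements.
#'
#' @param ctrl 4D array `[n1, n2, n3, 3]` of control displacements (mm),
#'   lattice axes in (x, z, y) order.
#' @param origin mm position of control point `[1, 1, 1]`.
#' @param spacing control-grid spacing mm (length 3, > 0).
#' @return An object of class `cc_field`.
#' @export
deformation_field <- function(ctrl, origin, spacing) {
  stopifnot(length(dim(ctrl)) == 4L, dim(ctrl)[4] == 3L,
            length(origin) == 3, length(spacing) == 3, all(spacing > 0))
  if (any(dim(ctrl)[1:3] < 4L))
    stop("control grid needs at least 4 points per axis for cubic support")
  structure(list(ctrl = ctrl, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "cc_field")
}

#' @export
print.cc_field <- function(x, ...) {
  cat("<cc_field> control grid", paste(dim(x$ctrl)[1:3], collapse = " x "),
      "at", paste(signif(x$spacing, 5), collapse = "/"), "mm; max |u| =",
      signif(max(abs(x$ctrl)), 5), "mm (bound)\n")
  invisible(x)
}

zero_field <- function(origin, spacing, n) {
  deformation_field(array(0, c(n, 3)), origin, spacing)
}

# scattered-point evaluation: accumulate the 4x4x4 tensor weights
field_eval <- function(field, pts) {
  pts <- rbind(pts)
  n <- nrow(pts)
  d <- dim(field$ctrl)[1:3]
  u <- matrix(0, n, 3)
  # continuous lattice coordinate (1-based)
  lc <- sweep(sweep(pts, 2, field$origin, "-"), 2, field$spacing, "/") + 1
  i0 <- floor(lc)
  fr <- lc - i0
  W <- lapply(1:3, function(ax) bspline_w(fr[, ax]))
  nc <- prod(d)
  for (a in 0:3) for (bb in 0:3) {
    wab <- W[[1]][, a + 1] * W[[2]][, bb + 1]
    ia <- pmin(pmax(i0[, 1] - 1 + a, 1L), d[1])
    jb <- pmin(pmax(i0[, 2] - 1 + bb, 1L), d[2])
    for (cc in 0:3) {
      w <- wab * W[[3]][, cc + 1]
      kc <- pmin(pmax(i0[, 3] - 1 + cc, 1L), d[3])
      base <- ia + (jb - 1) * d[1] + (kc - 1) * d[1] * d[2]
      u[, 1] <- u[, 1] + w * field$ctrl[base]
      u[, 2] <- u[, 2] + w * field$ctrl[base + nc]
      u[, 3] <- u[, 3] + w * field$ctrl[base + 2 * nc]
    }
  }
  u
}

# per-axis basis matrix for a regular sample grid (rows: samples, cols: ctrl)
bspline_basis_matrix <- function(coords, origin, spacing, n_ctrl) {
  lc <- (coords - origin) / spacing + 1
  i0 <- floor(lc)
  W <- bspline_w(lc - i0)
  M <- matrix(0, length(coords), n_ctrl)
  for (a in 0:3) {
    idx <- pmin(pmax(i0 - 1 + a, 1L), n_ctrl)
    M[cbind(seq_along(coords), idx)] <- M[cbind(seq_along(coords), idx)] + W[, a + 1]
  }
  M
}

# apply matrix M along the given axis of a 3D array
tensor_apply <- function(M, arr, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(arr, perm)
  dp <- dim(ap)
  res <- M %*% matrix(ap, nrow = dp[1])
  res <- array(res, c(nrow(M), dp[2], dp[3]))
  aperm(res, order(perm))
}

# separable field evaluation on a regular grid; returns list of 3 arrays
field_eval_grid <- function(field, xs, zs, ys) {
  d <- dim(field$ctrl)[1:3]
  M1 <- bspline_basis_matrix(xs, field$origin[1], field$spacing[1], d[1])
  M2 <- bspline_basis_matrix(zs, field$origin[2], field$spacing[2], d[2])
  M3 <- bspline_basis_matrix(ys, field$origin[3], field$spacing[3], d[3])
  lapply(1:3, function(comp) {
    a <- field$ctrl[, , , comp]
    dim(a) <- d
    tensor_apply(M3, tensor_apply(M2, tensor_apply(M1, a, 1), 2), 3)
  })
}

# adjoint of field_eval_grid: project per-grid-point weights onto the lattice
field_project_grid <- function(g, basis) {
  tensor_apply(t(basis[[3]]),
               tensor_apply(t(basis[[2]]),
                            tensor_apply(t(basis[[1]]), g, 1), 2), 3)
}

# ---------------------------------------------------------------------------
# composite transform: T(x) = affine(x) + u(x)

#' Composite spatial transform (affine plus optional elastic field)
#'
#' The map `T(x) = A x + b + u(x)` with `u` a \code{\link{deformation_field}}
#' (zero if absent), in the resampling convention: `T` maps reference-image
#' points into the floating-image domain.
#'
#' @param affine a `cc_affine` (default identity).
#' @param field an optional `cc_field`.
#' @return An object of class `cc_transform`.
#' @export
cc_transform <- function(affine = affine_transform(), field = NULL) {
  stopifnot(inherits(affine, "cc_affine"),
            is.null(field) || inherits(field, "cc_field"))
  structure(list(affine = affine, field = field), class = "cc_transform")
}

#' Apply a transform to physical points
#' @param t a `cc_transform`, `cc_affine` or `cc_field`.
#' @param pts n x 3 matrix of (x, z, y) mm points.
#' @return n x 3 matrix of mapped points.
#' @export
apply_transform <- function(t, pts) {
  pts <- rbind(pts)
  if (inherits(t, "cc_affine")) return(apply_affine(t, pts))
  if (inherits(t, "cc_field")) return(pts + field_eval(t, pts))
  stopifnot(inherits(t, "cc_transform"))
  out <- apply_affine(t$affine, pts)
  if (!is.null(t$field)) out <- out + field_eval(t$field, pts)
  out
}

#' Invert a spatial transform
#'
#' Affine maps are inverted analytically. Composite elastic maps are inverted
#' pointwise by fixed-point iteration on `x = A^{-1}(y - u(x))`, which
#' converges for the bounded, smooth fields used here; iteration stops when
#' the update is below `tol` mm.
#'
#' @param t a `cc_affine` or `cc_transform`.
#' @param pts for elastic maps, the points at which the inverse is needed
#'   (n x 3 mm). Affine inversion ignores `pts` and returns a transform.
#' @param tol convergence tolerance, mm.
#' @param max_iter maximum fixed-point iterations.
#' @return For affine input, the inverse transform object; for composite
#'   input, the n x 3 matrix of preimages of `pts`.
#' @export
invert_transform <- function(t, pts = NULL, tol = 1e-4, max_iter = 100L) {
  if (inherits(t, "cc_affine")) return(invert_affine(t))
  stopifnot(inherits(t, "cc_transform"))
  if (is.null(t$field)) return(cc_transform(invert_affine(t$affine)))
  if (is.null(pts))
    stop("inverting an elastic transform is pointwise: supply pts")
  pts <- rbind(pts)
  Ainv <- invert_affine(t$affine)
  x <- apply_affine(Ainv, pts)
  for (it in seq_len(max_iter)) {
    u <- field_eval(t$field, x)
    xn <- apply_affine(Ainv, pts - u)
    step <- max(abs(xn - x))
    x <- xn
    if (step < tol) return(x)
  }
  warning("fixed-point inversion did not reach tol = ", tol,
          " (last step ", signif(step, 3), " mm)")
  x
}

#' Numerically check that a transform is locally invertible on a domain
#'
#' Central-difference Jacobian determinants on a sample grid over the given
#' physical bounds; all determinants must be positive for the map to be
#' orientation-preserving (hence locally invertible).
#'
#' @param t transform accepted by \code{\link{apply_transform}}.
#' @param lower,upper length-3 mm bounds of the domain.
#' @param n samples per axis (default 7).
#' @param h finite-difference step mm.
#' @return Minimum Jacobian determinant over the sample grid.
#' @export
min_jacobian <- function(t, lower, upper, n = 7L, h = 0.5) {
  gr <- expand.grid(x = seq(lower[1], upper[1], length.out = n),
                    z = seq(lower[2], upper[2], length.out = n),
                    y = seq(lower[3], upper[3], length.out = n))
  p <- as.matrix(gr)
  J <- array(0, c(nrow(p), 3, 3))
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- h
    fp <- apply_transform(t, sweep(p, 2, e, "+"))
    fm <- apply_transform(t, sweep(p, 2, e, "-"))
    J[, , ax] <- (fp - fm) / (2 * h)
  }
  dets <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  min(dets)
}

#' Serialize a transform to JSON
#' @param t a `cc_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "cc_transform"))
  payload <- list(
    format = "contourcast-transform", version = 1L, axes = cc_axes(),
    units = "mm",
    affine = list(A = t$affine$A, b = t$affine$b),
    field = if (!is.null(t$field)) list(
      origin = t$field$origin, spacing = t$field$spacing,
      dim = dim(t$field$ctrl)[1:3], ctrl = as.numeric(t$field$ctrl)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform written by \code{\link{write_transform_json}}
#' @param path JSON path.
#' @return A `cc_transform`.
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "contourcast-transform"))
    stop("not a contourcast transform file: ", path)
  aff <- affine_from_matrix(matrix(unlist(j$affine$A), 3, 3), j$affine$b)
  fld <- NULL
  if (!is.null(j$field$ctrl))
    fld <- deformation_field(array(j$field$ctrl, c(j$field$dim, 3)),
                             j$field$origin, j$field$spacing)
  cc_transform(aff, fld)
}
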