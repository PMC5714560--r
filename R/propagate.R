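#' Propagate contours through an estimated transform
#'
#' Maps each contour point of the planning (floating-image) structure into
#' the reference (follow-up) image through the \emph{inverse} of the
#' estimated resampling map `T` (which maps reference points into the
#' floating domain): propagated points satisfy `T(x) = p`. Affine maps are
#' inverted analytically; elastic maps pointwise by fixed-point iteration.
#'
#' When the mapped slices stay planar and no target slice grid is requested,
#' the polygons are mapped point-by-point and returned as-is. Otherwise the
#' propagated surface is rebuilt (tessellation of the mapped vertices) and
#' re-sliced onto the reference slice grid by casting in-plane rays from the
#' mapped centroid — for the star-shaped slices this parameterization
#' presumes, this is the plane–mesh intersection expressed radially.
#'
#' Points that leave the support of the elastic field are extrapolated with
#' the affine part alone, with a warning.
#'
#' @param cs a `contour_set` on the floating (planning) image.
#' @param t a `cc_affine` or `cc_transform` estimated with the planning CT
#'   as floating image.
#' @param slice_ys optional numeric vector: slice y coordinates (mm) of the
#'   reference grid to re-slice onto.
#' @param n_points points per output contour when re-slicing.
#' @return A propagated `contour_set`.
#' @export
propagate_contours <- function(cs, t, slice_ys = NULL, n_points = 64L) {
  stopifnot(is_contour_set(cs))
  if (inherits(t, "cc_affine")) t <- cc_transform(t)
  stopifnot(inherits(t, "cc_transform"))

  map_back <- function(pts) {
    if (is.null(t$field)) {
      apply_affine(invert_affine(t$affine), pts)
    } else {
      x <- invert_transform(t, pts)
      # support check: affine extrapolation outside the field lattice
      lat_n <- dim(t$field$ctrl)[1:3]
      lc <- sweep(sweep(x, 2, t$field$origin, "-"), 2, t$field$spacing, "/") + 1
      out <- lc < 1 | lc > matrix(lat_n, nrow(lc), 3, byrow = TRUE)
      bad <- rowSums(out) > 0
      if (any(bad)) {
        warning(sum(bad), " propagated points left the elastic ROI; ",
                "extrapolated affinely")
        x[bad, ] <- apply_affine(invert_affine(t$affine),
                                 pts[bad, , drop = FALSE])
      }
      x
    }
  }

  mapped_slices <- lapply(cs$slices, function(s)
    map_back(cbind(s$points, s$y)))
  spread <- max(vapply(mapped_slices, function(m)
    diff(range(m[, 3])), numeric(1)))

  if (is.null(slice_ys) && spread < 1e-9) {
    # slice planes preserved: keep the polygons point-mapped
    return(contour_set(lapply(mapped_slices, function(m)
      list(y = m[1, 3], points = m[, 1:2, drop = FALSE])),
      structure = cs$structure, frame_of_reference = cs$frame_of_reference,
      observer = cs$observer))
  }

  mesh <- tessellate(cs, n_ring = max(n_points, 64L))
  mesh <- map_mesh(mesh, map_back)
  yr <- range(mesh$vertices[, 3])
  if (is.null(slice_ys)) {
    sp <- stats::median(diff(contour_slice_ys(cs)))
    slice_ys <- seq(yr[1], yr[2], by = sp)
  }
  phi <- (seq_len(n_points) - 1) / n_points * 2 * pi
  slices <- list()
  eps <- 1e-6 * max(diff(yr), 1)
  for (y in slice_ys) {
    if (y < yr[1] - 1e-9 || y > yr[2] + 1e-9) next
    # slices landing exactly on a cap plane are cast just inside the mesh,
    # so terminal slices are kept (their radii equal the cap ring)
    rho <- surface_slice_radii(mesh, min(max(y, yr[1] + eps), yr[2] - eps), phi)
    if (is.null(rho)) next
    ctr <- colMeans(mesh$vertices)
    slices[[length(slices) + 1L]] <-
      list(y = y, points = cbind(ctr[1] + rho * cos(phi),
                                 ctr[2] + rho * sin(phi)))
  }
  if (length(slices) < 2L)
    stop("propagated surface intersects fewer than 2 reference slices")
  contour_set(slices, structure = cs$structure,
              frame_of_reference = cs$frame_of_reference,
              observer = cs$observer)
}
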