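#' Per-slice closed contour set for one structure by one observer
#'
#' Ordered per-slice closed polygons in patient mm coordinates. Each slice
#' holds its y coordinate (superior–inferior axis) and an ordered closed
#' polygon of (x, z) points; the last point is implicitly joined to the
#' first. Slices are stored sorted by y.
#'
#' @param slices list; each element a list with `y` (scalar mm) and `points`
#'   (n x 2 matrix of (x, z) mm, n >= 3, non-self-intersecting).
#' @param structure name of the delineated structure (e.g. "prostate").
#' @param frame_of_reference frame-of-reference identifier shared by all
#'   slices.
#' @param observer optional observer identifier (provenance).
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(slices, structure = "prostate",
                        frame_of_reference = "local", observer = NA_character_) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("slices must be a non-empty list")
  slices <- lapply(slices, function(s) {
    pts <- as.matrix(s$points)
    storage.mode(pts) <- "double"
    if (ncol(pts) != 2L) stop("slice points must be an n x 2 (x, z) matrix")
    if (nrow(pts) < 3L) stop("each slice polygon needs at least 3 points")
    if (any(!is.finite(pts)) || !is.finite(s$y))
      stop("contour coordinates must be finite")
    if (polygon_self_intersects(pts))
      stop("self-intersecting polygon at slice y = ", signif(s$y, 6))
    list(y = as.numeric(s$y), points = unname(pts))
  })
  ys <- vapply(slices, `[[`, numeric(1), "y")
  slices <- slices[order(ys)]
  structure(list(structure = structure,
                 frame_of_reference = frame_of_reference,
                 observer = observer,
                 slices = slices),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  ys <- contour_slice_ys(x)
  cat("<contour_set> '", x$structure, "', ", length(x$slices), " slices, y in [",
      signif(min(ys), 5), ", ", signif(max(ys), 5), "] mm\n", sep = "")
  invisible(x)
}

is_contour_set <- function(x) inherits(x, "contour_set")

#' Slice y coordinates of a contour set
#' @param cs a `contour_set`.
#' @return Numeric vector of slice y positions (mm), ascending.
#' @export
contour_slice_ys <- function(cs) vapply(cs$slices, `[[`, numeric(1), "y")

#' All contour points as a 3-column (x, z, y) matrix
#' @param cs a `contour_set`.
#' @return n x 3 matrix of mm coordinates.
#' @export
contour_points_3d <- function(cs) {
  do.call(rbind, lapply(cs$slices, function(s)
    cbind(s$points, s$y)))
}

# O(n^2) proper-crossing test between non-adjacent closed-polygon edges
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4L) return(FALSE)
  p1 <- pts
  p2 <- pts[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]        # edge n..1 is adjacent to edge 1..2
    if (!length(js)) next
    a1 <- p1[i, ]; a2 <- p2[i, ]
    d <- a2 - a1
    b1 <- p1[js, , drop = FALSE]; b2 <- p2[js, , drop = FALSE]
    cross <- function(ux, uz, vx, vz) ux * vz - uz * vx
    d1 <- cross(d[1], d[2], b1[, 1] - a1[1], b1[, 2] - a1[2])
    d2 <- cross(d[1], d[2], b2[, 1] - a1[1], b2[, 2] - a1[2])
    e <- b2 - b1
    d3 <- cross(e[, 1], e[, 2], a1[1] - b1[, 1], a1[2] - b1[, 2])
    d4 <- cross(e[, 1], e[, 2], a2[1] - b1[, 1], a2[2] - b1[, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

polygon_signed_area <- function(pts) {
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2]) / 2
}

polygon_centroid <- function(pts) {
  # area-weighted centroid of a simple closed polygon
  n <- nrow(pts); nxt <- c(2:n, 1L)
  cr <- pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(pts))
  c(sum((pts[, 1] + pts[nxt, 1]) * cr), sum((pts[, 2] + pts[nxt, 2]) * cr)) / (6 * a)
}

#' Write contour sets to the JSON interchange format
#'
#' Plain-text interchange with an explicit axis-convention header, used for
#' fixtures, documentation and stage hand-off; RT-STRUCT is available for
#' interoperability (\code{\link{write_rtstruct}}).
#'
#' @param css a `contour_set` or list of them.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_contours_json <- function(css, path) {
  if (is_contour_set(css)) css <- list(css)
  stopifnot(all(vapply(css, is_contour_set, logical(1))))
  payload <- list(
    format = "contourcast-contours",
    version = 1L,
    axes = cc_axes(),
    units = "mm",
    note = "slice y = superior-inferior coordinate; points are (x, z) in-plane",
    contour_sets = lapply(css, function(cs) list(
      structure = cs$structure,
      frame_of_reference = cs$frame_of_reference,
      observer = cs$observer,
      slices = lapply(cs$slices, function(s)
        list(y = s$y, points = unname(s$points)))
    )))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read contour sets from the JSON interchange format
#' @param path `.json` file written by \code{\link{write_contours_json}}.
#' @return A list of `contour_set` objects.
#' @export
read_contours_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(j$format, "contourcast-contours"))
    stop("not a contourcast contour interchange file: ", path)
  if (!identical(as.character(j$axes), cc_axes()))
    stop("unexpected axis convention header: ", paste(j$axes, collapse = ","))
  lapply(j$contour_sets, function(el) {
    contour_set(lapply(el$slices, function(s)
      list(y = s$y, points = matrix(unlist(s$points), ncol = 2))),
      structure = el$structure,
      frame_of_reference = el$frame_of_reference,
      observer = el$observer %||% NA_character_)
  })
}
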