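#' Closed triangle mesh reconstructed from slice contours
#'
#' Construct from \code{\link{tessellate}}; `vertices` is an n x 3 (x, z, y)
#' mm matrix, `triangles` an m x 3 matrix of 1-based vertex indices with
#' consistent outward orientation.
#'
#' @name surface_mesh
NULL

new_surface_mesh <- function(vertices, triangles, provenance = list()) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3,
            is.matrix(triangles), ncol(triangles) == 3)
  if (any(!is.finite(vertices))) stop("mesh vertices must be finite")
  structure(list(vertices = vertices, triangles = triangles,
                 provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh>", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

# resample a closed polygon to n points by arc length, starting at the
# point where the boundary crosses azimuth 0 from the polygon centroid
resample_polygon <- function(pts, n) {
  if (polygon_signed_area(pts) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  ctr <- polygon_centroid(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]) %% (2 * pi)
  start <- which.min(ang)
  m <- nrow(pts)
  ord <- c(start:m, seq_len(start - 1L))
  p <- pts[ord, , drop = FALSE]
  p <- rbind(p, p[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polygon: zero perimeter")
  tq <- (seq_len(n) - 1) / n * total
  out <- matrix(0, n, 2)
  j <- 1L
  for (i in seq_len(n)) {
    while (s[j + 1L] < tq[i]) j <- j + 1L
    f <- (tq[i] - s[j]) / max(s[j + 1L] - s[j], 1e-300)
    out[i, ] <- p[j, ] + f * (p[j + 1L, ] - p[j, ])
  }
  out
}

#' Tessellate slice contours into a closed triangle mesh
#'
#' A simple tessellation: each slice polygon is resampled to `n_ring` points
#' by arc length (counter-clockwise, starting near azimuth 0 from the slice
#' centroid), consecutive rings are stitched with the cyclic correspondence
#' of minimal total twist, and the apex/base are closed with centroid fans.
#'
#' @param cs a `contour_set` with at least 2 slices.
#' @param n_ring points per resampled ring (default 64).
#' @return A closed `surface_mesh` (every edge shared by exactly two
#'   triangles, consistently oriented, outward normals).
#' @export
tessellate <- function(cs, n_ring = 64L) {
  stopifnot(is_contour_set(cs))
  ns <- length(cs$slices)
  if (ns < 2L)
    stop("tessellation needs at least 2 slices (got ", ns, ")")
  rings <- lapply(cs$slices, function(s) resample_polygon(s$points, n_ring))
  ys <- contour_slice_ys(cs)
  # minimal-twist correspondence: cyclic shift minimizing distance to the
  # previous ring
  for (i in 2:ns) {
    a <- rings[[i - 1L]]; b <- rings[[i]]
    costs <- vapply(0:(n_ring - 1L), function(off) {
      idx <- ((seq_len(n_ring) - 1L + off) %% n_ring) + 1L
      sum((a - b[idx, ])^2)
    }, numeric(1))
    off <- which.min(costs) - 1L
    idx <- ((seq_len(n_ring) - 1L + off) %% n_ring) + 1L
    rings[[i]] <- b[idx, , drop = FALSE]
  }
  verts <- do.call(rbind, lapply(seq_len(ns), function(i)
    cbind(rings[[i]], ys[i])))
  tri <- list()
  for (i in seq_len(ns - 1L)) {
    b0 <- (i - 1L) * n_ring
    j <- seq_len(n_ring); jn <- c(2:n_ring, 1L)
    tri[[length(tri) + 1L]] <- cbind(b0 + j, b0 + n_ring + j, b0 + jn)
    tri[[length(tri) + 1L]] <- cbind(b0 + jn, b0 + n_ring + j, b0 + n_ring + jn)
  }
  # caps: centroid fans at first (smallest y) and last ring
  c1 <- c(colMeans(rings[[1L]]), ys[1L])
  c2 <- c(colMeans(rings[[ns]]), ys[ns])
  v1 <- nrow(verts) + 1L; v2 <- nrow(verts) + 2L
  verts <- rbind(verts, c1, c2)
  j <- seq_len(n_ring); jn <- c(2:n_ring, 1L)
  tri[[length(tri) + 1L]] <- cbind(v1, j, jn)
  b0 <- (ns - 1L) * n_ring
  tri[[length(tri) + 1L]] <- cbind(v2, b0 + jn, b0 + j)
  mesh <- new_surface_mesh(unname(verts), do.call(rbind, tri),
                           provenance = list(observer = cs$observer,
                                             structure = cs$structure))
  if (mesh_volume(mesh) < 0)
    mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

#' Check mesh closedness and orientation consistency
#' @param mesh a `surface_mesh`.
#' @return TRUE if every undirected edge is shared by exactly 2 triangles and
#'   every directed edge appears exactly once (consistent orientation).
#' @export
mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  directed <- paste(ed[, 1], ed[, 2])
  if (any(duplicated(directed))) return(FALSE)
  und <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(und) == 2L)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @return Numeric scalar.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], ] - v[tr[, 1], ]
  e2 <- v[tr[, 3], ] - v[tr[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Signed enclosed volume of a mesh (mm^3, positive for outward orientation)
#' @param mesh a `surface_mesh`.
#' @return Numeric scalar.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], ]; b <- v[tr[, 2], ]; ccc <- v[tr[, 3], ]
  sum(a[, 1] * (b[, 2] * ccc[, 3] - b[, 3] * ccc[, 2]) -
        a[, 2] * (b[, 1] * ccc[, 3] - b[, 3] * ccc[, 1]) +
        a[, 3] * (b[, 1] * ccc[, 2] - b[, 2] * ccc[, 1])) / 6
}

#' Apply a point transform to mesh vertices
#' @param mesh a `surface_mesh`.
#' @param f function mapping an n x 3 matrix to an n x 3 matrix.
#' @return The transformed `surface_mesh`.
#' @export
map_mesh <- function(mesh, f) {
  new_surface_mesh(f(mesh$vertices), mesh$triangles, mesh$provenance)
}

#' @export
surface_slice_radii.surface_mesh <- function(surface, y, phi) {
  ctr <- colMeans(surface$vertices)
  yr <- range(surface$vertices[, 3])
  if (y <= yr[1] || y >= yr[2]) return(NULL)
  origin <- c(ctr[1], ctr[2], y)
  dirs <- cbind(cos(phi), sin(phi), 0)
  hit <- rays_intersect(surface, origin, dirs)
  if (anyNA(hit$distance)) return(NULL)
  hit$distance
}

#' Export a mesh as ASCII PLY (for external inspection)
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param scalars optional per-vertex scalar attached as a `quality` property.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               if (!is.null(scalars)) "property float quality",
               paste("element face", nt),
               "property list uchar int vertex_indices", "end_header"), con)
  vm <- mesh$vertices
  if (!is.null(scalars)) vm <- cbind(vm, scalars)
  utils::write.table(vm, con, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
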