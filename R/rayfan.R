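#' Build the radial ray fan used to sample segmentation surfaces
#'
#' Casts `n_elevation * n_azimuth` unit direction vectors from a shared
#' origin (the pooled prostate centre of mass, CMP). Elevation is sampled at
#' the midpoints of `n_elevation` equal bins of (0°, 180°) — midpoints honour
#' the strict bounds, so the poles are excluded — and azimuth at
#' `n_azimuth` equal steps starting from 0°. The default 32 x 64 = 2048
#' directions at constant angular step in both angles.
#'
#' @param cmp length-3 (x, z, y) mm origin of the fan.
#' @param n_elevation number of elevation steps (default 32).
#' @param n_azimuth number of azimuth steps (default 64).
#' @return An object of class `ray_fan`: origin, an n x 3 matrix of unit
#'   `directions` and the per-ray `elevation_deg` / `azimuth_deg`.
#' @export
make_ray_fan <- function(cmp, n_elevation = 32L, n_azimuth = 64L) {
  n_elevation <- as.integer(n_elevation); n_azimuth <- as.integer(n_azimuth)
  if (n_elevation < 1L || n_azimuth < 1L)
    stop("n_elevation and n_azimuth must be positive")
  stopifnot(length(cmp) == 3, all(is.finite(cmp)))
  elev <- (seq_len(n_elevation) - 0.5) / n_elevation * 180
  azim <- (seq_len(n_azimuth) - 1) / n_azimuth * 360
  g <- expand.grid(azimuth = azim, elevation = elev)  # azimuth fastest
  th <- g$elevation * pi / 180
  ph <- g$azimuth * pi / 180
  dirs <- sph_dir(th, ph)
  dirs <- dirs / sqrt(rowSums(dirs^2))   # exact unit norm
  structure(list(origin = as.numeric(cmp), directions = dirs,
                 elevation_deg = g$elevation, azimuth_deg = g$azimuth),
            class = "ray_fan")
}

#' @export
print.ray_fan <- function(x, ...) {
  cat("<ray_fan>", nrow(x$directions), "rays from (",
      paste(signif(x$origin, 5), collapse = ", "), ") mm\n")
  invisible(x)
}

#' First intersection of rays with a closed triangle mesh
#'
#' Moller–Trumbore ray–triangle intersection, evaluated for every triangle
#' of the mesh (exhaustive scan) and reduced to the first (smallest positive)
#' hit per ray. For star-shaped meshes sampled from an interior origin every
#' ray hits exactly once; rays with several crossings are flagged.
#'
#' @param mesh a `surface_mesh`.
#' @param origin length-3 mm ray origin (must be inside the mesh).
#' @param dirs n x 3 matrix of unit ray directions.
#' @param check_inside verify the origin lies inside the mesh (parity of
#'   crossings along +x) and error otherwise.
#' @return A list: `distance` (mm of first hit per ray, NA if none),
#'   `n_hits` (crossing count per ray), `multi` (logical flag).
#' @export
rays_intersect <- function(mesh, origin, dirs, check_inside = FALSE) {
  v <- mesh$vertices; tr <- mesh$triangles
  v0 <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - v0
  e2 <- v[tr[, 3], , drop = FALSE] - v0
  tvec <- sweep(v0, 2, origin, "-") * (-1)   # origin - v0
  n <- nrow(dirs)
  dist <- rep(NA_real_, n)
  nhits <- integer(n)
  eps <- 1e-12
  cross_rows <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  qvec <- cross_rows(tvec, e1)
  for (i in seq_len(n)) {
    d <- dirs[i, ]
    pvec <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
                  d[3] * e2[, 1] - d[1] * e2[, 3],
                  d[1] * e2[, 2] - d[2] * e2[, 1])
    det <- rowSums(e1 * pvec)
    ok <- abs(det) > eps
    inv <- ifelse(ok, 1 / det, 0)
    u <- rowSums(tvec * pvec) * inv
    vv <- (qvec[, 1] * d[1] + qvec[, 2] * d[2] + qvec[, 3] * d[3]) * inv
    tt <- rowSums(e2 * qvec) * inv
    hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & tt > 1e-9
    if (any(hit)) {
      # rays grazing shared edges/vertices register in several adjacent
      # triangles at the same distance: count distinct crossing distances
      ts <- sort(tt[hit])
      distinct <- c(TRUE, diff(ts) > 1e-6 * pmax(ts[-length(ts)], 1))
      nhits[i] <- sum(distinct)
      dist[i] <- ts[1]
    }
  }
  if (check_inside) {
    # irrational-ish direction avoids seams shared with the mesh lattice
    pd <- c(0.8694802, 0.3276091, 0.3700627)
    par <- rays_intersect(mesh, origin, matrix(pd, 1), check_inside = FALSE)
    if (par$n_hits %% 2 == 0)
      stop("ray origin lies outside the mesh")
  }
  list(distance = dist, n_hits = nhits, multi = nhits > 1L)
}

#' Cast a ray fan against a mesh and return per-ray distances
#'
#' @param mesh a `surface_mesh` enclosing the fan origin.
#' @param fan a `ray_fan`.
#' @return Numeric vector of first-hit distances (mm), one per ray, with a
#'   `multi` attribute flagging rays with several crossings.
#' @export
cast_fan <- function(mesh, fan) {
  res <- rays_intersect(mesh, fan$origin, fan$directions, check_inside = TRUE)
  if (anyNA(res$distance))
    stop("internal error: ", sum(is.na(res$distance)),
         " rays found no intersection on a closed mesh")
  structure(res$distance, multi = res$multi)
}
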