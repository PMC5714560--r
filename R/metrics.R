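#' Pooled centre of mass of the prostate (CMP)
#'
#' Arithmetic mean of all contour points pooled across all observers'
#' contour sets of one image; the shared origin from which the radial ray
#' fan is cast.
#'
#' @param contour_sets a `contour_set` or non-empty list of them.
#' @return Length-3 (x, z, y) mm point.
#' @export
compute_cmp <- function(contour_sets) {
  if (is_contour_set(contour_sets)) contour_sets <- list(contour_sets)
  if (length(contour_sets) == 0L) stop("need at least one contour set")
  stopifnot(all(vapply(contour_sets, is_contour_set, logical(1))))
  pts <- do.call(rbind, lapply(contour_sets, contour_points_3d))
  colMeans(pts)
}

#' Radial distances of each observer's surface along a shared ray fan
#'
#' Tessellates every contour set and intersects it with the fan; all
#' observers are sampled from the same CMP so the per-ray populations are
#' comparable.
#'
#' @param contour_sets list of `contour_set` (one per observer).
#' @param fan a `ray_fan`.
#' @param n_ring tessellation ring resolution.
#' @return n_rays x n_observers matrix of distances (mm); attribute
#'   `multi_hits` gives the per-observer count of flagged rays.
#' @export
observer_distance_matrix <- function(contour_sets, fan, n_ring = 64L) {
  stopifnot(length(contour_sets) >= 1L)
  cols <- lapply(contour_sets, function(cs) cast_fan(tessellate(cs, n_ring), fan))
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(seq_along(contour_sets), function(i)
    contour_sets[[i]]$observer %||% paste0("obs", i), character(1))
  attr(m, "multi_hits") <- vapply(cols, function(d) sum(attr(d, "multi")), integer(1))
  m
}

#' Average surface and local variability along the ray fan
#'
#' For each ray: the mean of the per-observer intersection distances (the
#' average segmentation surface in radial form), the deviations of each
#' observer from that mean, their sample (n-1 denominator) standard
#' deviation, and the absolute (x, z, y) components of the deviation
#' vectors, obtained by projecting the signed radial deviation onto the ray
#' direction.
#'
#' @param distances n_rays x n_observers matrix from
#'   \code{\link{observer_distance_matrix}} (>= 2 observers, no missing
#'   rays).
#' @param fan the `ray_fan` the distances were sampled on.
#' @return A `radial_sample_table`: a list with `table` (data.frame: ray,
#'   elevation_deg, azimuth_deg, mean_mm, sd_mm), `distances`, `deviations`
#'   (signed, n_rays x n_obs) and `axis_abs` (n_rays x n_obs x 3 absolute
#'   components).
#' @export
average_surface_and_variability <- function(distances, fan) {
  distances <- as.matrix(distances)
  if (ncol(distances) < 2L) stop("need at least 2 observers")
  if (anyNA(distances)) stop("missing ray coverage in distance matrix")
  if (any(distances <= 0)) stop("distances must be positive")
  n <- nrow(distances)
  if (n != nrow(fan$directions))
    stop("distance matrix and ray fan disagree on the number of rays")
  mu <- rowMeans(distances)
  dev <- distances - mu
  sdv <- sqrt(rowSums(dev^2) / (ncol(distances) - 1))
  axis_abs <- array(0, c(n, ncol(distances), 3))
  for (k in 1:3)
    axis_abs[, , k] <- abs(dev * fan$directions[, k])
  tab <- data.frame(ray = seq_len(n),
                    elevation_deg = fan$elevation_deg,
                    azimuth_deg = fan$azimuth_deg,
                    mean_mm = mu, sd_mm = sdv)
  structure(list(table = tab, distances = distances, deviations = dev,
                 axis_abs = axis_abs, fan = fan),
            class = "radial_sample_table")
}

#' @export
print.radial_sample_table <- function(x, ...) {
  cat("<radial_sample_table>", nrow(x$distances), "rays x",
      ncol(x$distances), "observers; pooled sd =",
      signif(sqrt(mean(x$table$sd_mm^2)), 4), "mm\n")
  invisible(x)
}

#' Pooled deviation summary across images (12-column layout)
#'
#' Pools the point deviations of one or more radial sample tables and
#' reports, per patient axis and for the 3D deviation magnitude, the mean,
#' standard deviation and maximum of the absolute deviations — the
#' X/Z/Y/3D x mean/std/max layout used to summarize segmentation
#' variability over all data.
#'
#' @param tables a `radial_sample_table` or list of them.
#' @return Named numeric vector with entries `x_mean, x_std, x_max, z_mean,
#'   z_std, z_max, y_mean, y_std, y_max, d3_mean, d3_std, d3_max` (mm).
#' @export
global_summary <- function(tables) {
  if (inherits(tables, "radial_sample_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  comp <- lapply(1:3, function(k)
    unlist(lapply(tables, function(t) as.numeric(t$axis_abs[, , k]))))
  d3 <- unlist(lapply(tables, function(t) as.numeric(abs(t$deviations))))
  out <- c(vapply(comp, function(v) c(mean(v), stats::sd(v), max(v)), numeric(3)),
           c(mean(d3), stats::sd(d3), max(d3)))
  names(out) <- c("x_mean", "x_std", "x_max", "z_mean", "z_std", "z_max",
                  "y_mean", "y_std", "y_max", "d3_mean", "d3_std", "d3_max")
  out
}

#' Export a radial sample table as CSV
#'
#' Columns: ray index, elevation, azimuth, one distance column per observer,
#' mean and standard deviation (all mm).
#'
#' @param rst a `radial_sample_table`.
#' @param path output `.csv`.
#' @return `path`, invisibly.
#' @export
write_radial_table_csv <- function(rst, path) {
  df <- cbind(rst$table[c("ray", "elevation_deg", "azimuth_deg")],
              as.data.frame(rst$distances),
              rst$table[c("mean_mm", "sd_mm")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
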