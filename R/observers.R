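#' Multi-observer contouring noise model
#'
#' Statistical model of expert clinicians delineating the prostate on axial
#' CT slices. Each observer's perturbation of the true boundary has two
#' parts, both applied radially \emph{in-plane} (clinicians contour slice by
#' slice, so their errors live in the slice plane):
#' \itemize{
#'  \item a smooth per-observer systematic bias over the surface — a random
#'    low-order spherical-harmonic-like function of (elevation, azimuth) with
#'    root-mean-square amplitude `bias_sigma_mm`, producing spatially
#'    coherent disagreement between observers;
#'  \item independent per-point radial noise with standard deviation
#'    `point_noise_sigma_mm * (1 + apex_base_inflation * |cos(elevation)|)` —
#'    inflated toward the superior/inferior poles, where 5 mm slice spacing
#'    makes the boundary genuinely ambiguous.
#' }
#' A repeat (long-term re-segmentation) pass adds an extra independent smooth
#' bias of amplitude `repeat_drift_sigma_mm` per observer.
#'
#' Calibration (closed form): pooled over the sphere, the expected per-ray
#' variance of the in-plane radial deviations is
#' `bias_sigma_mm^2 + point_noise_sigma_mm^2 * mean(infl(theta)^2)`, where
#' `infl(theta) = 1 + apex_base_inflation * |cos(theta)|`; the bias basis is
#' normalized to unit mean square over the sphere. A 3D radial deviation
#' measured along a ray at elevation `theta` relates to the in-plane
#' deviation by the factor `sin(theta)`.
#'
#' @param n_observers number of observers (>= 2; default 5).
#' @param bias_sigma_mm RMS amplitude of the smooth per-observer bias (mm).
#' @param point_noise_sigma_mm per-point radial noise sigma (mm).
#' @param apex_base_inflation pole inflation coefficient (0 = uniform noise).
#' @param repeat_drift_sigma_mm extra smooth drift for a repeat pass (mm).
#' @param seed integer seed.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(n_observers = 5L,
                           bias_sigma_mm = 1.2,
                           point_noise_sigma_mm = 0.8,
                           apex_base_inflation = 1.5,
                           repeat_drift_sigma_mm = 1.0,
                           seed = 1L) {
  n_observers <- as.integer(n_observers)
  stopifnot(n_observers >= 2L, bias_sigma_mm >= 0, point_noise_sigma_mm >= 0,
            apex_base_inflation >= 0, repeat_drift_sigma_mm >= 0)
  structure(list(n_observers = n_observers, bias_sigma_mm = bias_sigma_mm,
                 point_noise_sigma_mm = point_noise_sigma_mm,
                 apex_base_inflation = apex_base_inflation,
                 repeat_drift_sigma_mm = repeat_drift_sigma_mm,
                 seed = as.integer(seed)),
            class = "observer_model")
}

# low-order smooth random function on the sphere with unit mean square;
# basis functions individually normalized to <psi^2> = 1 over the uniform
# sphere measure, coefficients iid N(0, 1/K)
smooth_sphere_fn <- function(seed) {
  set.seed(seed)
  K <- 7L
  cf <- rnorm(K, 0, sqrt(1 / K))
  function(theta, phi) {
    st <- sin(theta); ct <- cos(theta)
    cf[1] * 1 +
      cf[2] * sqrt(3) * ct +
      cf[3] * sqrt(3) * st * cos(phi) +
      cf[4] * sqrt(3) * st * sin(phi) +
      cf[5] * sqrt(5) * (3 * ct^2 - 1) / 2 +
      cf[6] * sqrt(15 / 4) * st^2 * cos(2 * phi) +
      cf[7] * sqrt(15 / 4) * st^2 * sin(2 * phi)
  }
}

#' Predicted pooled in-plane radial deviation sigma of an observer model
#'
#' Closed-form calibration target: the square root of the pooled per-ray
#' variance of in-plane radial deviations implied by the model parameters
#' (sphere-averaged; see \code{\link{observer_model}}).
#'
#' @param obs an `observer_model`.
#' @return Pooled sigma in mm.
#' @export
observer_pooled_sigma <- function(obs) {
  # mean over the uniform sphere of (1 + k |cos(theta)|)^2 = 1 + k + k^2/3
  k <- obs$apex_base_inflation
  infl2 <- 1 + k + k^2 / 3
  sqrt(obs$bias_sigma_mm^2 + obs$point_noise_sigma_mm^2 * infl2)
}

# in-plane radius of a sliceable surface at height y, azimuths phi (vector).
# For a radial_surface: solve sqrt(rho^2 + h^2) = r(theta(rho), phi) per phi.
# Returns NULL if the slice does not intersect the surface for every phi.
surface_slice_radii <- function(surface, y, phi) {
  UseMethod("surface_slice_radii")
}

#' @export
surface_slice_radii.radial_surface <- function(surface, y, phi) {
  h <- y - surface$center[3]
  rmax <- max(surface$radius(rep(pi / 2, 64), seq(0, 2 * pi, length.out = 64)))
  rpole <- surface$radius(if (h <= 0) 0 else pi, 0)
  if (abs(h) >= rpole) return(NULL)
  vapply(phi, function(p) {
    f <- function(rho) {
      R <- sqrt(rho^2 + h^2)
      R - surface$radius(acos(pmin(pmax(h / R, -1), 1)), p)
    }
    lo <- 1e-9
    hi <- 2.5 * rmax
    if (f(lo) >= 0 || f(hi) <= 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }, numeric(1))
}

#' Simulate per-observer slice contours of a true surface
#'
#' Slices the true prostate surface on a CT-like axial slice grid and
#' perturbs each observer's contours according to the
#' \code{\link{observer_model}}: smooth systematic bias plus independent
#' pole-inflated radial noise, applied in-plane. Deterministic given the
#' model seed (and `pass`).
#'
#' @param surface a `radial_surface` (or `surface_mesh`) that is star-shaped
#'   with respect to its centre.
#' @param obs an `observer_model`.
#' @param slice_spacing_mm axial slice spacing (mm), e.g. the CT slice
#'   thickness.
#' @param slice_ys optional explicit slice y coordinates (mm) of the image
#'   being contoured (e.g. `axis_coords(vol, 3)`); clinicians contour on the
#'   acquisition's own slices. Default: a grid at `slice_spacing_mm` centred
#'   on the structure.
#' @param n_points contour points per slice (default 64).
#' @param pass 1 for the first contouring session; 2 (or higher) simulates a
#'   long-term repeat session with extra drift `repeat_drift_sigma_mm`.
#' @param image_id identifier of the image being contoured. Each observer's
#'   systematic bias persists across images (the same clinicians contour the
#'   whole CT series), while the per-point noise and any repeat drift are
#'   drawn freshly per image and pass.
#' @param frame_of_reference frame id stamped on the output contour sets.
#' @return A list of `contour_set`, one per observer.
#' @export
simulate_observer_contours <- function(surface, obs, slice_spacing_mm,
                                       n_points = 64L, pass = 1L,
                                       image_id = "img",
                                       slice_ys = NULL,
                                       frame_of_reference = "local") {
  stopifnot(inherits(obs, "observer_model"), slice_spacing_mm > 0)
  ctr <- surface_center(surface)
  if (is.null(slice_ys)) {
    # candidate slice grid aligned to the centre, CT-like
    kmax <- ceiling(120 / slice_spacing_mm)
    ys <- ctr[3] + (-kmax:kmax) * slice_spacing_mm
  } else {
    ys <- sort(slice_ys)
  }
  phi <- (seq_len(n_points) - 1) / n_points * 2 * pi
  slice_rho <- lapply(ys, function(y) {
    rho <- surface_slice_radii(surface, y, phi)
    if (is.null(rho) || anyNA(rho)) NULL else rho
  })
  if (!any(!vapply(slice_rho, is.null, logical(1))))
    stop("slice spacing ", slice_spacing_mm,
         " mm is larger than the surface extent: no slices intersect")
  # true pole extents (superior pole is theta = 0, the +y direction)
  r_top_true <- surface_pole_radius(surface, top = TRUE)
  r_bot_true <- surface_pole_radius(surface, top = FALSE)

  lapply(seq_len(obs$n_observers), function(o) {
    bias <- smooth_sphere_fn(substream_seed(obs$seed, paste0("bias-", o)))
    drift <- if (pass > 1L && obs$repeat_drift_sigma_mm > 0)
      smooth_sphere_fn(substream_seed(obs$seed,
                                      paste0("drift-", o, "-", pass, "-", image_id)))
    else NULL
    set.seed(substream_seed(obs$seed,
                            paste0("noise-", o, "-", pass, "-", image_id)))
    bias_at <- function(theta, phi) {
      b <- obs$bias_sigma_mm * bias(theta, phi)
      if (!is.null(drift)) b <- b + obs$repeat_drift_sigma_mm * drift(theta, phi)
      b
    }
    # terminal-slice selection: the observer includes an axial slice when it
    # falls inside their perceived apex/base extent — the dominant source of
    # superior-inferior disagreement with 5 mm slices
    pole_sigma <- obs$point_noise_sigma_mm * (1 + obs$apex_base_inflation)
    r_top_p <- max(r_top_true + bias_at(0, 0) + pole_sigma * rnorm(1),
                   0.6 * slice_spacing_mm)
    r_bot_p <- max(r_bot_true + bias_at(pi, 0) + pole_sigma * rnorm(1),
                   0.6 * slice_spacing_mm)
    slices <- list()
    for (i in seq_along(ys)) {
      h <- ys[i] - ctr[3]
      if (h >= 0 && h >= r_top_p) next
      if (h < 0 && -h >= r_bot_p) next
      if (is.null(slice_rho[[i]])) {
        # slice beyond the true pole that the observer still includes:
        # a small extrapolated cap contour
        r_side <- if (h >= 0) r_top_p else r_bot_p
        if (abs(h) >= r_side) next
        rho_o <- rep(max(sqrt(r_side^2 - h^2), 0.8), length(phi))
      } else {
        rho <- slice_rho[[i]]
        R <- sqrt(rho^2 + h^2)
        theta <- acos(pmin(pmax(h / R, -1), 1))
        b <- bias_at(theta, phi)
        infl <- 1 + obs$apex_base_inflation * abs(cos(theta))
        eps <- rnorm(length(phi), 0, 1) * obs$point_noise_sigma_mm * infl
        rho_o <- pmax(rho + b + eps, 0.5)  # keep polygons simple and positive
      }
      slices[[length(slices) + 1L]] <-
        list(y = ys[i],
             points = cbind(ctr[1] + rho_o * cos(phi), ctr[2] + rho_o * sin(phi)))
    }
    if (length(slices) < 2L)
      stop("observer ", o, " retained fewer than 2 slices; slice spacing too ",
           "coarse for the structure")
    contour_set(slices, structure = "prostate",
                frame_of_reference = frame_of_reference,
                observer = paste0("obs", o))
  })
}

# radial extent of a surface at its superior (+y) or inferior pole
surface_pole_radius <- function(surface, top = TRUE) {
  if (inherits(surface, "radial_surface"))
    return(surface$radius(if (top) 0 else pi, 0))
  ctr <- colMeans(surface$vertices)
  d <- if (top) c(0, 0, 1) else c(0, 0, -1)
  hit <- rays_intersect(surface, ctr, matrix(d, 1))
  hit$distance[1]
}

surface_center <- function(surface) {
  if (inherits(surface, "radial_surface")) return(surface$center)
  if (inherits(surface, "surface_mesh")) return(colMeans(surface$vertices))
  stop("unsupported surface type")
}
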