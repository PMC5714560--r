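#' Specification of a synthetic pelvic CT phantom
#'
#' Stylized deformable pelvic anatomy: an ellipsoidal prostate with an
#' optional smooth boundary perturbation, a spherical bladder superior to it,
#' and a posterior rectal tube carrying an air balloon, embedded in a soft
#' tissue body cylinder. The defaults mirror a helical single-slice pelvic
#' acquisition: 0.9766 mm in-plane pixels and 5 mm slices, with a 40 cm3
#' rectal air balloon. The anatomy is deliberately stylized — the evaluation
#' machinery needs contrast boundaries and a known truth surface, not
#' anatomical realism.
#'
#' @param grid_shape voxels per axis (x, z, y). The default covers a reduced
#'   prostate-centred field of view rather than a full 512 x 512 pelvis.
#' @param spacing_mm physical voxel spacing (x, z, y) in mm.
#' @param prostate_semiaxes_mm ellipsoid semi-axes (x, z, y) of the prostate.
#' @param prostate_shape_amp amplitude of the smooth multiplicative boundary
#'   perturbation (0 = exact ellipsoid; must stay < 0.15 to keep the surface
#'   star-shaped with margin).
#' @param bladder_radius_mm bladder sphere radius.
#' @param rectum_radius_mm outer radius of the rectal tube.
#' @param balloon_air_cm3 rectal balloon air volume (cm3); sets the length of
#'   the intra-rectal air cylinder.
#' @param hu per-tissue mean intensities (HU): `background`, `body`,
#'   `prostate`, `bladder`, `rectum_wall`, `air`.
#' @param texture_amp amplitude (HU) of smooth band-limited intensity
#'   texture inside the body (gives the registration features to lock onto).
#' @param noise_sigma iid Gaussian intensity noise sigma (HU).
#' @param seed integer seed; the generator is bit-deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160L, 160L, 36L),
                         spacing_mm = c(0.9766, 0.9766, 5.0),
                         prostate_semiaxes_mm = c(23, 19, 21),
                         prostate_shape_amp = 0.05,
                         bladder_radius_mm = 26,
                         rectum_radius_mm = 17,
                         balloon_air_cm3 = 40,
                         hu = c(background = -1000, body = 20, prostate = 60,
                                bladder = 0, rectum_wall = 45, air = -1000),
                         texture_amp = 12,
                         noise_sigma = 4,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            length(prostate_semiaxes_mm) == 3, all(prostate_semiaxes_mm > 0),
            prostate_shape_amp >= 0, prostate_shape_amp < 0.15,
            bladder_radius_mm >= 0, rectum_radius_mm >= 0, balloon_air_cm3 >= 0,
            texture_amp >= 0, noise_sigma >= 0)
  needed <- c("background", "body", "prostate", "bladder", "rectum_wall", "air")
  if (!all(needed %in% names(hu))) stop("hu must name: ", paste(needed, collapse = ", "))
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 prostate_semiaxes_mm = as.numeric(prostate_semiaxes_mm),
                 prostate_shape_amp = prostate_shape_amp,
                 bladder_radius_mm = bladder_radius_mm,
                 rectum_radius_mm = rectum_radius_mm,
                 balloon_air_cm3 = balloon_air_cm3,
                 hu = hu, texture_amp = texture_amp,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Star-shaped surface given by a radial function
#'
#' A closed surface defined as `p = center + r(theta, phi) d(theta, phi)`
#' with elevation `theta` from the +y (superior) pole and azimuth `phi` in
#' the axial (x, z) plane. Any surface defined this way is star-shaped with
#' respect to `center` by construction.
#'
#' @param center length-3 mm.
#' @param radius_fn vectorized function `(theta_rad, phi_rad) -> mm` (> 0).
#' @return An object of class `radial_surface`.
#' @export
radial_surface <- function(center, radius_fn) {
  stopifnot(length(center) == 3, is.function(radius_fn))
  structure(list(center = as.numeric(center), radius = radius_fn),
            class = "radial_surface")
}

# unit direction for elevation theta (from +y pole) and azimuth phi,
# components ordered (x, z, y)
sph_dir <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# spherical angles of points relative to a centre; returns theta, phi, r
sph_angles <- function(pts, center) {
  d <- sweep(rbind(pts), 2, center, "-")
  r <- sqrt(rowSums(d^2))
  theta <- acos(pmin(pmax(ifelse(r > 0, d[, 3] / r, 1), -1), 1))
  phi <- atan2(d[, 2], d[, 1]) %% (2 * pi)
  list(theta = theta, phi = phi, r = r)
}

# smooth multiplicative shape perturbation, pole-regular by construction
prostate_shape_fn <- function(semi, amp, seed) {
  if (amp == 0) {
    return(function(theta, phi) {
      d <- sph_dir(theta, phi)
      1 / sqrt((d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2)
    })
  }
  set.seed(substream_seed(seed, "prostate-shape"))
  ph <- runif(3, 0, 2 * pi)
  w <- rnorm(3); w <- w / sqrt(sum(w^2))
  function(theta, phi) {
    d <- sph_dir(theta, phi)
    base <- 1 / sqrt((d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2)
    st <- sin(theta); ct <- cos(theta)
    g <- 1 + amp * (w[1] * st^2 * cos(2 * phi + ph[1]) +
                      w[2] * st * ct * cos(phi + ph[2]) +
                      w[3] * st^2 * sin(2 * phi + ph[3]))
    base * g
  }
}

# smooth band-limited 3D texture: a few random cosine waves
texture_field <- function(coords, amp, seed) {
  if (amp == 0) return(0)
  set.seed(substream_seed(seed, "texture"))
  n_waves <- 8L
  k <- matrix(rnorm(3 * n_waves), n_waves, 3)
  k <- k / sqrt(rowSums(k^2)) * runif(n_waves, 2 * pi / 80, 2 * pi / 25)
  ph <- runif(n_waves, 0, 2 * pi)
  w <- rnorm(n_waves); w <- w / sqrt(sum(w^2))
  tex <- 0
  for (i in seq_len(n_waves))
    tex <- tex + w[i] * cos(coords %*% k[i, ] + ph[i])
  amp * sqrt(2) * as.numeric(tex)
}

#' Generate a synthetic pelvic CT phantom
#'
#' Builds the stylized anatomy of a \code{\link{phantom_spec}} on its voxel
#' grid and returns both the CT volume and the exact ground-truth prostate
#' surface as a radial function, so downstream contouring, registration and
#' evaluation can be scored against a known truth.
#'
#' @param spec a `phantom_spec`.
#' @return A list with `volume` (a `ct_volume`), `surface` (a
#'   `radial_surface` for the prostate boundary) and `organs` (centres used,
#'   mm).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$spacing_mm
  fov <- (d - 1) * sp
  ctr <- fov / 2                       # grid centre, origin at 0
  xs <- (seq_len(d[1]) - 1) * sp[1]
  zs <- (seq_len(d[2]) - 1) * sp[2]
  ys <- (seq_len(d[3]) - 1) * sp[3]

  semi <- spec$prostate_semiaxes_mm
  pc <- ctr                            # prostate at grid centre
  bl_c <- ctr + c(0, -0.18 * fov[2], -(semi[3] + spec$bladder_radius_mm + 6))
  re_c_xz <- ctr[1:2] + c(0, semi[2] + spec$rectum_radius_mm + 5)
  balloon_r <- max(spec$rectum_radius_mm - 3, 1)
  balloon_len <- if (spec$balloon_air_cm3 > 0)
    spec$balloon_air_cm3 * 1000 / (pi * balloon_r^2) else 0

  # interiority / disjointness checks, naming the offending organ
  if (any(pc - semi < 4) || any(pc + semi > fov - 4))
    stop("prostate geometry exceeds the grid interior")
  has_bladder <- spec$bladder_radius_mm > 0
  has_rectum <- spec$rectum_radius_mm > 0
  if (has_bladder) {
    if (bl_c[3] - spec$bladder_radius_mm < 0 ||
        any(abs(bl_c[1:2] - ctr[1:2]) + spec$bladder_radius_mm > fov[1:2]))
      stop("bladder geometry exceeds the grid")
    if (sqrt(sum((bl_c - pc)^2)) < spec$bladder_radius_mm + max(semi))
      stop("bladder overlaps prostate: organ regions must be disjoint")
  }
  if (has_rectum) {
    if (re_c_xz[2] + spec$rectum_radius_mm > fov[2])
      stop("rectum geometry exceeds the grid")
    gap_rect <- re_c_xz[2] - spec$rectum_radius_mm - (pc[2] + semi[2])
    if (gap_rect < 0) stop("rectum overlaps prostate: organ regions must be disjoint")
  }

  shape <- prostate_shape_fn(semi, spec$prostate_shape_amp, spec$seed)
  surface <- radial_surface(pc, shape)

  # voxel coordinate grids (recycled vectors, no expand.grid copy)
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Z <- array(rep(rep(zs, each = d[1]), times = d[3]), d)
  Y <- array(rep(ys, each = d[1] * d[2]), d)

  hu <- spec$hu
  a <- array(hu[["background"]], d)

  # body: elliptic cylinder along y
  body <- ((X - ctr[1]) / (0.48 * fov[1]))^2 + ((Z - ctr[2]) / (0.44 * fov[2]))^2 <= 1
  a[body] <- hu[["body"]]

  if (has_bladder) {
    bl <- (X - bl_c[1])^2 + (Z - bl_c[2])^2 + (Y - bl_c[3])^2 <= spec$bladder_radius_mm^2
    a[bl & body] <- hu[["bladder"]]
  }

  if (has_rectum) {
    r2_xz <- (X - re_c_xz[1])^2 + (Z - re_c_xz[2])^2
    rect <- r2_xz <= spec$rectum_radius_mm^2
    a[rect & body] <- hu[["rectum_wall"]]
    if (balloon_len > 0) {
      airm <- r2_xz <= balloon_r^2 & abs(Y - ctr[3]) <= balloon_len / 2
      a[airm & body] <- hu[["air"]]
    }
  }

  # prostate: radial-function interior test inside its bounding box
  dx <- X - pc[1]; dz <- Z - pc[2]; dy <- Y - pc[3]
  rr <- sqrt(dx^2 + dz^2 + dy^2)
  inbb <- rr <= max(semi) * (1 + spec$prostate_shape_amp) + 1
  ang <- sph_angles(cbind(dx[inbb], dz[inbb], dy[inbb]), c(0, 0, 0))
  inside <- ang$r <= shape(ang$theta, ang$phi)
  pros <- inbb
  pros[inbb] <- inside
  a[pros] <- hu[["prostate"]]

  if (spec$texture_amp > 0) {
    tex <- texture_field(cbind(as.numeric(X), as.numeric(Z), as.numeric(Y)),
                         spec$texture_amp, spec$seed)
    a[body] <- a[body] + array(tex, d)[body]
  }
  if (spec$noise_sigma > 0) {
    set.seed(substream_seed(spec$seed, "noise"))
    a <- a + array(rnorm(prod(d), 0, spec$noise_sigma), d)
  }

  list(volume = ct_volume(a, sp, origin = c(0, 0, 0)),
       surface = surface,
       organs = list(prostate_center = pc, bladder_center = bl_c,
                     rectum_center_xz = re_c_xz, prostate_mask = pros))
}
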