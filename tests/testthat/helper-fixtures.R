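# shared fixtures, built in code at test time

circle_slice <- function(y, R = 25, n = 64, c_xz = c(0, 0)) {
  r <- sqrt(max(R^2 - y^2, 0))
  a <- (seq_len(n) - 1) / n * 2 * pi
  list(y = y, points = cbind(c_xz[1] + r * cos(a), c_xz[2] + r * sin(a)))
}

# sphere sliced at bin midpoints (the CT slicing convention: a slice
# represents +/- half a slice thickness of tissue)
sphere_contours <- function(R = 25, spacing = 5, n = 64, center = c(0, 0, 0),
                            observer = "obs1") {
  ys <- seq(-R + spacing / 2, R - spacing / 2, by = spacing)
  contour_set(lapply(ys, function(dy) {
    s <- circle_slice(dy, R = R, n = n, c_xz = center[1:2])
    s$y <- dy + center[3]
    s
  }), observer = observer)
}

sphere_surface <- function(R = 25, center = c(0, 0, 0)) {
  radial_surface(center, function(theta, phi) rep(R, length(theta)))
}

ellipsoid_surface <- function(semi, center = c(0, 0, 0)) {
  radial_surface(center, function(theta, phi) {
    d <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    1 / sqrt((d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2)
  })
}

# independent ray-triangle oracle: plane intersection + inside-test via
# normal-aligned edge cross products (different formulation and loop
# structure than the package's Moller-Trumbore scan)
brute_force_distances <- function(mesh, origin, dirs) {
  v <- mesh$vertices; tr <- mesh$triangles
  n_ray <- nrow(dirs)
  best <- rep(Inf, n_ray)
  for (k in seq_len(nrow(tr))) {
    a <- v[tr[k, 1], ]; b <- v[tr[k, 2], ]; cc <- v[tr[k, 3], ]
    nrm <- c((b[2]-a[2])*(cc[3]-a[3]) - (b[3]-a[3])*(cc[2]-a[2]),
             (b[3]-a[3])*(cc[1]-a[1]) - (b[1]-a[1])*(cc[3]-a[3]),
             (b[1]-a[1])*(cc[2]-a[2]) - (b[2]-a[2])*(cc[1]-a[1]))
    denom <- dirs %*% nrm
    tt <- as.numeric(((a - origin) %*% nrm)) / as.numeric(denom)
    tt[abs(denom) < 1e-12] <- Inf
    tt[tt <= 1e-9] <- Inf
    p <- sweep(dirs * ifelse(is.finite(tt), tt, 0), 2, origin, "+")
    edge_side <- function(p0, p1) {
      e <- p1 - p0
      w <- sweep(p, 2, p0, "-")
      cx <- e[2] * w[, 3] - e[3] * w[, 2]
      cy <- e[3] * w[, 1] - e[1] * w[, 3]
      cz <- e[1] * w[, 2] - e[2] * w[, 1]
      cx * nrm[1] + cy * nrm[2] + cz * nrm[3]
    }
    inside <- edge_side(a, b) >= -1e-9 & edge_side(b, cc) >= -1e-9 &
      edge_side(cc, a) >= -1e-9
    hit <- is.finite(tt) & inside & tt < best
    best[hit] <- tt[hit]
  }
  best[!is.finite(best)] <- NA_real_
  best
}

# memoised registration fixtures (shared across test files; each is a full
# phantom study at reduced grid so the whole suite stays fast)
.fx <- new.env(parent = emptyenv())

test_phantom_spec <- function(seed = 5) {
  phantom_spec(grid_shape = c(80, 80, 28), spacing_mm = c(1.8, 1.8, 5),
               prostate_semiaxes_mm = c(22, 18, 20),
               bladder_radius_mm = 16, rectum_radius_mm = 11,
               balloon_air_cm3 = 12, seed = seed)
}

test_reg_config <- function() {
  registration_config(levels = 2L, elastic_ctrl_spacing_mm = c(20, 10),
                      target_samples = 20000L)
}

reg_fixture <- function() {
  if (!is.null(.fx$reg)) return(.fx$reg)
  ph <- generate_phantom(test_phantom_spec())
  roi <- roi_around(surface_to_mesh(ph$surface), 20)
  cfg <- test_reg_config()

  tr_truth <- ground_truth_deformation(translation_mm = c(4, -3, 5), seed = 2)
  tr_def <- deform_phantom(ph$volume, tr_truth)
  aff_tr <- register_affine(tr_def$volume, ph$volume, roi, cfg)

  sc_truth <- ground_truth_deformation(scale = c(1.05, 1.05, 1.05), seed = 3)
  sc_def <- deform_phantom(ph$volume, sc_truth)
  aff_sc <- register_affine(sc_def$volume, ph$volume, roi, cfg)

  el_truth <- ground_truth_deformation(translation_mm = c(2, -1, 2),
                                       rotation_deg = c(1, 0.5, -1),
                                       elastic_amplitude_mm = 4, seed = 7)
  el_def <- deform_phantom(ph$volume, el_truth)
  aff_el <- register_affine(el_def$volume, ph$volume, roi, cfg)
  ela_el <- register_elastic(el_def$volume, ph$volume, aff_el, roi, cfg)

  fu_mesh <- map_mesh(surface_to_mesh(ph$surface),
                      function(v) invert_transform(el_def$transform, v))
  vv <- fu_mesh$vertices
  t_true <- apply_transform(el_def$transform, vv)
  epe <- function(t) mean(sqrt(rowSums((apply_transform(t, vv) - t_true)^2)))

  .fx$reg <- list(phantom = ph, roi = roi, cfg = cfg,
                  tr_truth = tr_truth, tr_def = tr_def, aff_tr = aff_tr,
                  sc_truth = sc_truth, aff_sc = aff_sc,
                  el_truth = el_truth, el_def = el_def,
                  aff_el = aff_el, ela_el = ela_el,
                  epe_affine = epe(cc_transform(aff_el)),
                  epe_elastic = epe(ela_el))
  .fx$reg
}

test_experiment_config <- function(seed, observers = list(),
                                   deformation = list(), intra = FALSE) {
  experiment_config(
    n_patients = 1L, n_fractions = 1L,
    phantom = list(grid_shape = c(80, 80, 28), spacing_mm = c(1.8, 1.8, 5),
                   prostate_semiaxes_mm = c(22, 18, 20),
                   bladder_radius_mm = 16, rectum_radius_mm = 11,
                   balloon_air_cm3 = 12),
    observers = observers, deformation = deformation,
    registration = list(levels = 2L, elastic_ctrl_spacing_mm = c(20, 10),
                        target_samples = 20000L),
    intra_arm = intra, seed = seed)
}
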