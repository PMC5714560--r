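test_that("ray fan has the required structure", {
  fan <- make_ray_fan(c(0, 0, 0))
  expect_equal(nrow(fan$directions), 2048L)
  expect_lt(max(abs(sqrt(rowSums(fan$directions^2)) - 1)), 1e-12)
  expect_lt(sqrt(sum(colSums(fan$directions)^2)), 1e-9)
  ug <- sort(unique(fan$elevation_deg))
  expect_equal(min(diff(ug)), 180 / 32)
  expect_gt(min(ug), 0); expect_lt(max(ug), 180)
  expect_error(make_ray_fan(c(0, 0, 0), n_elevation = 0), "positive")
})

test_that("CMP is the pooled mean of all contour points", {
  sq <- contour_set(list(list(y = 5, points = rbind(c(8, 18), c(12, 18),
                                                    c(12, 22), c(8, 22)))))
  expect_equal(compute_cmp(sq), c(10, 20, 5), ignore_attr = TRUE)
  expect_equal(compute_cmp(list(sq, sq)), compute_cmp(sq))
  expect_error(compute_cmp(list()), "at least one")
})

test_that("CMP of noisy observer spheres recovers the true centre", {
  # five observers = true sphere slices plus 1 mm in-plane radial noise
  set.seed(5)
  ctr <- c(10, -5, 40)
  css <- lapply(1:5, function(o) {
    cs <- sphere_contours(R = 25, spacing = 5, center = ctr,
                          observer = paste0("obs", o))
    cs$slices <- lapply(cs$slices, function(s) {
      v <- sweep(s$points, 2, ctr[1:2])
      rho <- sqrt(rowSums(v^2))
      s$points <- sweep(v * (1 + rnorm(length(rho)) / rho), 2, ctr[1:2], "+")
      s
    })
    cs
  })
  expect_lt(sqrt(sum((compute_cmp(css) - ctr)^2)), 0.5)
})

test_that("tessellation reproduces analytic prism area and sphere volume", {
  sq <- function(y) list(y = y, points = cbind(c(-10, 10, 10, -10),
                                               c(-10, -10, 10, 10)))
  prism <- tessellate(contour_set(list(sq(0), sq(20))))
  expect_true(mesh_is_closed(prism))
  expect_lt(abs(mesh_area(prism) - 2400) / 2400, 0.01)
  expect_equal(mesh_volume(prism), 8000, tolerance = 1e-6)

  sph <- tessellate(sphere_contours(R = 25, spacing = 5))
  expect_true(mesh_is_closed(sph))
  expect_lt(abs(mesh_volume(sph) - 4 / 3 * pi * 25^3) / (4 / 3 * pi * 25^3),
            0.05)
})

test_that("tessellation rejects degenerate input", {
  expect_error(tessellate(contour_set(list(circle_slice(0)))), "2 slices")
})

test_that("simulated observer meshes are closed with edge degree exactly 2", {
  surf <- sphere_surface(R = 25)
  css <- simulate_observer_contours(surf, observer_model(seed = 8), 5)
  for (cs in css) expect_true(mesh_is_closed(tessellate(cs)))
})

test_that("ray casting matches analytic sphere and ellipsoid radii", {
  fan <- make_ray_fan(c(0, 0, 0))
  sph <- surface_to_mesh(sphere_surface(25))
  d <- cast_fan(sph, fan)
  expect_lt(max(abs(d - 25) / 25), 0.005)

  semi <- c(25, 18, 30)
  ell <- surface_to_mesh(ellipsoid_surface(semi))
  d2 <- cast_fan(ell, fan)
  th <- fan$elevation_deg * pi / 180; phi <- fan$azimuth_deg * pi / 180
  analytic <- 1 / sqrt((sin(th) * cos(phi) / semi[1])^2 +
                         (sin(th) * sin(phi) / semi[2])^2 +
                         (cos(th) / semi[3])^2)
  expect_lt(max(abs(d2 - analytic) / analytic), 0.01)
})

test_that("ray casting equals the brute-force all-triangle oracle", {
  mesh <- surface_to_mesh(ellipsoid_surface(c(20, 15, 25)), n_elev = 16,
                          n_azim = 24)
  fan <- make_ray_fan(c(1, -2, 0.5))   # off-centre origin
  d <- cast_fan(mesh, fan)
  oracle <- brute_force_distances(mesh, fan$origin, fan$directions)
  expect_equal(as.numeric(d), oracle, tolerance = 1e-9)
})

test_that("an origin outside the mesh errors", {
  mesh <- surface_to_mesh(sphere_surface(10))
  expect_error(cast_fan(mesh, make_ray_fan(c(50, 0, 0))), "outside")
})

test_that("average surface and variability match hand arithmetic", {
  fan <- make_ray_fan(c(0, 0, 0), n_elevation = 1, n_azimuth = 1)
  rst <- average_surface_and_variability(cbind(24, 26), fan)
  expect_equal(rst$table$mean_mm, 25)
  expect_equal(as.numeric(rst$deviations), c(-1, 1))
  expect_equal(rst$table$sd_mm, sqrt(2), tolerance = 1e-12)
})

test_that("identical observers give zero variability; mean deviations vanish", {
  surf <- sphere_surface(25)
  mesh <- surface_to_mesh(surf)
  fan <- make_ray_fan(c(0, 0, 0))
  d <- cast_fan(mesh, fan)
  rst <- average_surface_and_variability(cbind(d, d, d), fan)
  expect_equal(max(rst$table$sd_mm), 0)
  expect_lt(max(abs(rowSums(rst$deviations))), 1e-9)
  expect_equal(rst$table$mean_mm, as.numeric(d))
})

test_that("deviation axis decomposition isolates a pure x shift on the +x ray", {
  # ray along +x: elevation 90 deg, azimuth 0
  fan <- make_ray_fan(c(0, 0, 0), n_elevation = 2, n_azimuth = 2)
  fan$directions <- rbind(c(1, 0, 0))
  fan$elevation_deg <- 90; fan$azimuth_deg <- 0
  rst <- average_surface_and_variability(cbind(24, 26), fan)
  expect_equal(as.numeric(rst$axis_abs[1, , 1]), c(1, 1))
  expect_equal(max(rst$axis_abs[1, , 2:3]), 0)
})

test_that("global summary matches hand arithmetic and is permutation invariant", {
  fan <- make_ray_fan(c(0, 0, 0), n_elevation = 1, n_azimuth = 1)
  fan$directions <- rbind(c(1, 0, 0))
  rst <- average_surface_and_variability(cbind(24, 26), fan)
  gs <- global_summary(rst)
  expect_equal(unname(gs[c("x_mean", "x_max", "z_mean", "y_mean", "d3_mean")]),
               c(1, 1, 0, 0, 1))
  # 3D magnitude dominates each axis component; max >= mean per column
  surf <- sphere_surface(25)
  css <- simulate_observer_contours(surf, observer_model(seed = 12), 5)
  fan2 <- make_ray_fan(compute_cmp(css))
  rst2 <- average_surface_and_variability(observer_distance_matrix(css, fan2),
                                          fan2)
  for (k in 1:3)
    expect_true(all(abs(rst2$deviations) >= rst2$axis_abs[, , k] - 1e-12))
  gs2 <- global_summary(rst2)
  expect_true(all(gs2[c("x_max", "z_max", "y_max", "d3_max")] >=
                    gs2[c("x_mean", "z_mean", "y_mean", "d3_mean")]))
  expect_equal(global_summary(list(rst, rst2)), global_summary(list(rst2, rst)))
  # all-zero deviations give an all-zero summary
  rst0 <- average_surface_and_variability(cbind(25, 25), fan)
  expect_equal(max(abs(global_summary(rst0))), 0)
})
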