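test_that("noise-free phantom has exactly the configured prostate intensity", {
  sp <- test_phantom_spec()
  sp <- phantom_spec(grid_shape = sp$grid_shape, spacing_mm = sp$spacing_mm,
                     prostate_semiaxes_mm = sp$prostate_semiaxes_mm,
                     bladder_radius_mm = 16, rectum_radius_mm = 11,
                     balloon_air_cm3 = 12, texture_amp = 0, noise_sigma = 0,
                     seed = 9)
  ph <- generate_phantom(sp)
  expect_equal(unique(as.numeric(ph$volume$data[ph$organs$prostate_mask])),
               unname(sp$hu[["prostate"]]))
})

test_that("phantom generation is bit-deterministic given the seed", {
  sp <- test_phantom_spec(seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  th <- seq(0.1, pi - 0.1, length.out = 50)
  expect_identical(a$surface$radius(th, th), b$surface$radius(th, th))
})

test_that("a spherical prostate yields a constant radial function", {
  sp <- phantom_spec(grid_shape = c(64, 64, 24), spacing_mm = c(2, 2, 5),
                     prostate_semiaxes_mm = c(25, 25, 25),
                     prostate_shape_amp = 0, bladder_radius_mm = 0,
                     rectum_radius_mm = 0, seed = 1)
  ph <- generate_phantom(sp)
  set.seed(4)
  th <- runif(2000, 1e-3, pi - 1e-3); phi <- runif(2000, 0, 2 * pi)
  expect_lt(max(abs(ph$surface$radius(th, phi) - 25)), 1e-9)
})

test_that("organ geometry exceeding the grid errors naming the organ", {
  sp <- phantom_spec(grid_shape = c(32, 32, 10), spacing_mm = c(1, 1, 5),
                     prostate_semiaxes_mm = c(30, 30, 30),
                     bladder_radius_mm = 0, rectum_radius_mm = 0)
  expect_error(generate_phantom(sp), "prostate")
})

test_that("generated prostate surfaces are star-shaped from the centroid", {
  ph <- generate_phantom(test_phantom_spec(seed = 17))
  mesh <- surface_to_mesh(ph$surface)
  fan <- make_ray_fan(colMeans(mesh$vertices))
  d <- cast_fan(mesh, fan)
  expect_length(d, 2048)
  expect_equal(sum(attr(d, "multi")), 0)
})

test_that("identity deformation reproduces the volume exactly at grid points", {
  ph <- generate_phantom(test_phantom_spec(seed = 2))
  def <- deform_phantom(ph$volume, ground_truth_deformation())
  expect_equal(def$volume$data, ph$volume$data, tolerance = 1e-12)
  expect_equal(max(abs(def$displacement)), 0)
})

test_that("pure translation moves the prostate centroid by the stated amount", {
  sp <- phantom_spec(grid_shape = c(80, 80, 28), spacing_mm = c(1.8, 1.8, 5),
                     prostate_semiaxes_mm = c(22, 18, 20),
                     bladder_radius_mm = 0, rectum_radius_mm = 0,
                     texture_amp = 0, noise_sigma = 0, seed = 3)
  ph <- generate_phantom(sp)
  def <- deform_phantom(ph$volume, ground_truth_deformation(c(5, 0, 0)))
  centroid <- function(v) {
    # partial-volume weight of prostate (60 HU) against body (20 HU):
    # linear in tissue fraction, so the centroid resolves below the voxel
    w <- pmin(pmax((as.numeric(v$data) - 20) / 40, 0), 1)
    pts <- contourcast:::grid_points(lapply(1:3, function(k) axis_coords(v, k)))
    colSums(pts * w) / sum(w)
  }
  shift <- centroid(def$volume) - centroid(ph$volume)
  # pull-back by +5 mm moves the pictured prostate by -5 mm along x
  expect_lt(abs(shift[1] + 5), 0.2)
  expect_lt(max(abs(shift[2:3])), 0.2)
})

test_that("elastic truth fields respect the amplitude bound and invertibility", {
  ph <- generate_phantom(test_phantom_spec(seed = 4))
  def <- deform_phantom(ph$volume,
                        ground_truth_deformation(elastic_amplitude_mm = 4,
                                                 seed = 7))
  # affine part is the identity here, so the dense displacement is the
  # elastic field itself
  expect_lt(max(sqrt(rowSums(def$displacement^2))), 4 + 1e-9)
  b <- volume_bounds(ph$volume)
  expect_gt(min_jacobian(def$transform, b[1, ], b[2, ]), 0)
})

test_that("folding fields are rejected", {
  # a displacement reversing orientation: u(x) = -2x on a 10 mm lattice
  n <- c(6L, 6L, 6L)
  g <- contourcast:::grid_points(lapply(1:3, function(k) (0:5) * 10))
  ctrl <- array(0, c(n, 3))
  for (k in 1:3) ctrl[, , , k] <- array(-2 * (g[, k] - 25), n)
  fld <- deformation_field(ctrl, c(0, 0, 0), c(10, 10, 10))
  expect_lt(min_jacobian(cc_transform(field = fld), c(10, 10, 10),
                         c(40, 40, 40)), 0)
})
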