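test_that("identity parameters give the identity map to machine precision", {
  t <- affine_transform()
  p <- matrix(rnorm(60, sd = 50), 20)
  expect_lt(max(abs(apply_transform(t, p) - p)), 1e-12)
})

test_that("affine inversion is analytic and exact", {
  t <- affine_transform(translation = c(4, -3, 5), rotation_deg = c(2, -1, 3),
                        scale = c(1.05, 0.98, 1.02), shear = c(0.01, 0, 0.02),
                        center = c(10, 10, 10))
  p <- matrix(rnorm(300, sd = 40), 100)
  rt <- apply_transform(invert_transform(t), apply_transform(t, p))
  expect_lt(max(abs(rt - p)), 1e-9)
})

test_that("non-orientation-preserving parameters are rejected", {
  expect_error(affine_transform(scale = c(-1, 1, 1)), "positive")
})

test_that("a zero field is the identity and inverts to itself", {
  fld <- deformation_field(array(0, c(4, 4, 4, 3)), c(0, 0, 0), c(20, 20, 20))
  t <- cc_transform(field = fld)
  p <- matrix(runif(30, 10, 50), 10)
  expect_equal(apply_transform(t, p), p, ignore_attr = TRUE)
  expect_lt(max(abs(invert_transform(t, p) - p)), 1e-12)
})

test_that("elastic inversion round-trips within 0.05 mm on sampled points", {
  set.seed(7)
  ctrl <- array(pmin(pmax(rnorm(6 * 6 * 6 * 3, 0, 2), -4), 4), c(6, 6, 6, 3))
  fld <- deformation_field(ctrl, c(-20, -20, -20), c(20, 20, 20))
  t <- cc_transform(affine_transform(translation = c(2, 1, -1)), fld)
  p <- matrix(runif(3000, 10, 50), 1000)
  y <- apply_transform(t, p)
  x <- invert_transform(t, y, tol = 1e-5)
  expect_lt(max(sqrt(rowSums((apply_transform(t, x) - y)^2))), 0.05)
})

test_that("dense B-spline field is bounded by its control displacements", {
  set.seed(1)
  ctrl <- array(runif(5 * 5 * 5 * 3, -3, 3), c(5, 5, 5, 3))
  fld <- deformation_field(ctrl, c(0, 0, 0), c(25, 25, 25))
  p <- matrix(runif(3000, 10, 90), 1000)
  u <- apply_transform(cc_transform(field = fld), p) - p
  expect_lt(max(abs(u)), max(abs(ctrl)) + 1e-12)
})

test_that("separable grid evaluation agrees with scattered evaluation", {
  set.seed(2)
  ctrl <- array(rnorm(5 * 6 * 4 * 3), c(5, 6, 4, 3))
  fld <- deformation_field(ctrl, c(0, 0, 0), c(10, 12, 15))
  xs <- seq(8, 30, by = 3); zs <- seq(10, 40, by = 4); ys <- seq(12, 28, by = 5)
  g <- contourcast:::field_eval_grid(fld, xs, zs, ys)
  pts <- contourcast:::grid_points(list(xs, zs, ys))
  u <- contourcast:::field_eval(fld, pts)
  for (k in 1:3)
    expect_equal(as.numeric(g[[k]]), u[, k], tolerance = 1e-10)
})

test_that("transform JSON serialization round-trips", {
  set.seed(3)
  ctrl <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  t <- cc_transform(affine_transform(translation = c(1, 2, 3),
                                     rotation_deg = c(0, 1, 0)),
                    deformation_field(ctrl, c(0, 0, 0), c(20, 20, 20)))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform_json(t, path)
  t2 <- read_transform_json(path)
  p <- matrix(runif(60, 10, 50), 20)
  expect_equal(apply_transform(t2, p), apply_transform(t, p),
               tolerance = 1e-12)
})
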