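test_that("zero-noise observers contour the true surface exactly", {
  surf <- sphere_surface(R = 25)
  obs <- observer_model(bias_sigma_mm = 0, point_noise_sigma_mm = 0,
                        apex_base_inflation = 0, repeat_drift_sigma_mm = 0,
                        seed = 1)
  css <- simulate_observer_contours(surf, obs, 5)
  expect_length(css, 5)
  for (cs in css) {
    r <- sqrt(rowSums(contour_points_3d(cs)^2))
    expect_lt(max(abs(r - 25)), 0.1)
  }
  # and all observers agree exactly
  expect_identical(contour_points_3d(css[[1]]), contour_points_3d(css[[5]]))
})

test_that("per-point noise calibrates to the configured sigma", {
  surf <- sphere_surface(R = 25)
  obs <- observer_model(n_observers = 8, bias_sigma_mm = 0,
                        point_noise_sigma_mm = 1.0, apex_base_inflation = 0,
                        seed = 2)
  css <- simulate_observer_contours(surf, obs, 2)
  res <- unlist(lapply(css, function(cs)
    lapply(cs$slices, function(s) {
      if (abs(s$y) > 24) return(NULL)      # skip extrapolated terminal caps
      sqrt(rowSums(s$points^2)) - sqrt(25^2 - s$y^2)
    })))
  expect_lt(abs(sd(res) - 1.0), 0.15)
})

test_that("pooled deviations match the documented closed-form calibration", {
  surf <- sphere_surface(R = 25)
  obs <- observer_model(n_observers = 10, bias_sigma_mm = 1.2,
                        point_noise_sigma_mm = 0.8, apex_base_inflation = 1.5,
                        seed = 7)
  css <- simulate_observer_contours(surf, obs, 2)
  res <- unlist(lapply(css, function(cs)
    lapply(cs$slices, function(s) {
      if (abs(s$y) > 24) return(NULL)
      sqrt(rowSums(s$points^2)) - sqrt(25^2 - s$y^2)
    })))
  predicted <- observer_pooled_sigma(obs)
  expect_lt(abs(sd(res) - predicted) / predicted, 0.2)
})

test_that("noise is inflated toward the superior-inferior poles", {
  surf <- sphere_surface(R = 25)
  obs <- observer_model(n_observers = 10, bias_sigma_mm = 0,
                        point_noise_sigma_mm = 0.8, apex_base_inflation = 2,
                        seed = 3)
  css <- simulate_observer_contours(surf, obs, 2)
  pole <- c(); equator <- c()
  for (cs in css) for (s in cs$slices) {
    if (abs(s$y) > 24) next
    r <- sqrt(rowSums(s$points^2)) - sqrt(25^2 - s$y^2)
    if (abs(s$y) > 18) pole <- c(pole, r)
    if (abs(s$y) < 6) equator <- c(equator, r)
  }
  expect_gt(sd(pole), 1.5 * sd(equator))
})

test_that("a repeat pass differs from the first by the drift model", {
  surf <- sphere_surface(R = 25)
  obs <- observer_model(repeat_drift_sigma_mm = 1.0, seed = 4)
  c1 <- simulate_observer_contours(surf, obs, 5, pass = 1L)
  c2 <- simulate_observer_contours(surf, obs, 5, pass = 2L)
  for (o in seq_along(c1)) {
    y1 <- contour_slice_ys(c1[[o]]); y2 <- contour_slice_ys(c2[[o]])
    shared <- intersect(y1, y2)
    d <- mean(vapply(shared, function(y)
      mean(abs(c1[[o]]$slices[[which(y1 == y)]]$points -
                 c2[[o]]$slices[[which(y2 == y)]]$points)), numeric(1)))
    expect_gt(d, 0)
  }
})

test_that("identical seeds reproduce contours bit-exactly", {
  surf <- sphere_surface(R = 25)
  obs <- observer_model(seed = 11)
  a <- simulate_observer_contours(surf, obs, 5, image_id = "x")
  b <- simulate_observer_contours(surf, obs, 5, image_id = "x")
  expect_identical(lapply(a, contour_points_3d), lapply(b, contour_points_3d))
})

test_that("too-coarse slice spacing errors", {
  surf <- sphere_surface(R = 10)
  obs <- observer_model(seed = 1)
  expect_error(simulate_observer_contours(surf, obs, 60), "slice")
})
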