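test_that("per-ray t-test matches stats::t.test and the closed form", {
  manual <- c(24, 25, 25, 25, 26)
  prop <- c(27, 28, 28, 28, 29)
  p <- as.numeric(per_ray_ttest(manual, prop))
  expect_equal(p, t.test(manual, prop, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  # closed-form pooled t with df = 8
  sp2 <- (4 * var(manual) + 4 * var(prop)) / 8
  tstat <- (mean(manual) - mean(prop)) / sqrt(sp2 * (2 / 5))
  expect_equal(p, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  # Welch option
  expect_equal(as.numeric(per_ray_ttest(manual, prop, var_equal = FALSE)),
               t.test(manual, prop)$p.value, tolerance = 1e-12)
})

test_that("p-values match a t-CDF oracle to 1e-9 across random fixtures", {
  set.seed(5)
  for (i in 1:50) {
    a <- rnorm(5, 25, runif(1, 0.2, 2)); b <- rnorm(5, 25.5, runif(1, 0.2, 2))
    expect_equal(as.numeric(per_ray_ttest(a, b)),
                 t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate rays follow the documented limits", {
  expect_equal(as.numeric(per_ray_ttest(rep(25, 5), rep(25, 5))), 1)
  expect_equal(as.numeric(per_ray_ttest(rep(25, 5), rep(25.05, 5))), 1)  # below resolution
  p0 <- per_ray_ttest(rep(25, 5), rep(27, 5))
  expect_equal(as.numeric(p0), 0)
  expect_true(attr(p0, "degenerate"))
  expect_equal(as.numeric(per_ray_ttest(c(24, 25, 25, 25, 26),
                                        c(24, 25, 25, 25, 26))), 1)
})

test_that("type-I error is calibrated at the nominal 0.05 level", {
  set.seed(123)
  n <- 1e4
  m1 <- matrix(rnorm(5 * n, 25, 1), n)
  m2 <- matrix(rnorm(5 * n, 25, 1), n)
  p <- ttest_rows(m1, m2)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("evaluate_propagation is structural: 2048 tests on 5-vs-5 populations", {
  fan <- make_ray_fan(c(0, 0, 0))
  set.seed(2)
  manual <- matrix(rnorm(2048 * 5, 25, 1), 2048)
  prop <- manual + rnorm(2048 * 5, 0, 0.3)
  ev <- evaluate_propagation(manual, prop, fan)
  expect_equal(ev$n_tests, 2048L)
  expect_length(ev$p, 2048)
  expect_equal(ev$pass_fraction, mean(ev$p >= 0.05))
  expect_equal(ev$expected_false_flags, 0.05 * 2048)
})

test_that("identical populations pass everywhere; a large shift fails everywhere", {
  fan <- make_ray_fan(c(0, 0, 0))
  set.seed(3)
  manual <- matrix(rnorm(2048 * 5, 25, 0.5), 2048)
  ev1 <- evaluate_propagation(manual, manual, fan)
  expect_equal(ev1$pass_fraction, 1)
  expect_true(all(ev1$p == 1))
  ev2 <- evaluate_propagation(manual, manual + 5, fan)
  expect_lt(ev2$pass_fraction, 0.01)
})

test_that("pass fraction decreases monotonically with injected bias", {
  fan <- make_ray_fan(c(0, 0, 0))
  set.seed(4)
  manual <- matrix(rnorm(2048 * 5, 25, 1), 2048)
  noise <- matrix(rnorm(2048 * 5, 0, 1), 2048)
  pf <- vapply(c(0, 1, 2, 5), function(b)
    evaluate_propagation(manual, manual + noise + b, fan)$pass_fraction,
    numeric(1))
  expect_true(all(diff(pf) <= 0))
})

test_that("intraobserver comparison flags inflated propagated variability", {
  set.seed(6)
  n <- 1000
  first <- matrix(rnorm(n * 5, 25, 1), n)
  second <- first + matrix(rnorm(n * 5, 0, 0.7), n)
  prop <- first + matrix(rnorm(n * 5, 0, 1.4), n)
  cmpr <- intraobserver_comparison(first, second, prop)
  # with five observers the exact flag probability for a 2x noise ratio is
  # P(F(4,4) > 1/4) ~= 0.895
  expect_gt(attr(cmpr, "flag_fraction"), 0.85)
  # degenerate: everything identical
  cmp0 <- intraobserver_comparison(first, first, first)
  expect_equal(max(cmp0$intra_sd), 0)
  expect_equal(max(cmp0$prop_sd), 0)
  expect_false(any(cmp0$intra_smaller))
  # observer ordering invariance
  perm <- sample(5)
  cmp_p <- intraobserver_comparison(first[, perm], second[, perm], prop[, perm])
  expect_equal(cmp_p$intra_sd, cmpr$intra_sd)
  expect_equal(cmp_p$intra_smaller, cmpr$intra_smaller)
  expect_error(intraobserver_comparison(first, NULL, prop), "second")
})

test_that("experiment summary pools designs and is permutation invariant", {
  fan <- make_ray_fan(c(0, 0, 0), n_elevation = 1, n_azimuth = 2)
  fan$directions <- rbind(c(1, 0, 0), c(-1, 0, 0))
  fan$elevation_deg <- c(90, 90); fan$azimuth_deg <- c(0, 180)
  manual <- rbind(c(24, 26), c(25, 25))
  rst <- average_surface_and_variability(manual, fan)
  ev_a <- evaluate_propagation(manual, manual + 1, fan)
  ev_e <- evaluate_propagation(manual, manual + 0.5, fan)
  s <- summarize_experiment(list(rst), list(ev_a), list(ev_e))
  expect_equal(rownames(s$summary), c("Segment", "Affine", "Elastic"))
  expect_equal(unname(s$summary["Segment", "x_mean"]), 0.5)  # devs 0, +/-1 on x rays
  expect_equal(unname(s$summary["Affine", "d3_mean"]),
               mean(abs(manual + 1 - rowMeans(manual))))
  # pooling is invariant to the order of the designs
  manual_b <- rbind(c(23, 27), c(25, 25))
  rst_b <- average_surface_and_variability(manual_b, fan)
  ev_ab <- evaluate_propagation(manual_b, manual_b + 2, fan)
  ev_eb <- evaluate_propagation(manual_b, manual_b + 1, fan)
  s_ab <- summarize_experiment(list(rst, rst_b), list(ev_a, ev_ab),
                               list(ev_e, ev_eb))
  s_ba <- summarize_experiment(list(rst_b, rst), list(ev_ab, ev_a),
                               list(ev_eb, ev_e))
  expect_equal(s_ab$summary, s_ba$summary)
  # all-zero deviations produce an all-zero row
  rst0 <- average_surface_and_variability(rbind(c(25, 25), c(25, 25)), fan)
  ev0 <- evaluate_propagation(rbind(c(25, 25), c(25, 25)),
                              rbind(c(25, 25), c(25, 25)), fan)
  s0 <- summarize_experiment(list(rst0), list(ev0), list(ev0))
  expect_equal(max(abs(s0$summary)), 0)
})
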