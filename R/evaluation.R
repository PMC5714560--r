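#' Per-ray two-tailed Student's t-test
#'
#' Two-sample pooled-variance (Student's) two-tailed t-test comparing, along
#' one ray, the manual observer distances with the propagated-contour
#' distances; optionally Welch's unequal-variance form. With the study
#' design of five observers per population the pooled test has 8 degrees of
#' freedom.
#'
#' Degenerate rays (both samples constant) are decided at a geometric
#' resolution floor: p = 1 when the two constants agree within
#' `degenerate_tol` mm (well below CT pixel size and contouring precision),
#' else the p = 0 limit, flagged via the `degenerate` attribute.
#'
#' @param manual numeric vector of manual distances (n >= 2).
#' @param propagated numeric vector of propagated distances (n >= 2).
#' @param var_equal pooled-variance Student form (default TRUE) or Welch.
#' @param degenerate_tol equality tolerance (mm) for zero-variance rays.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
per_ray_ttest <- function(manual, propagated, var_equal = TRUE,
                          degenerate_tol = 0.1) {
  p <- ttest_rows(matrix(manual, 1), matrix(propagated, 1),
                  var_equal = var_equal, degenerate_tol = degenerate_tol)
  structure(as.numeric(p), degenerate = attr(p, "degenerate")[1])
}

#' Row-wise two-sample t-tests
#'
#' Vectorized form of \code{\link{per_ray_ttest}}: one test per row (ray).
#'
#' @param m1,m2 matrices (rays x observers), >= 2 columns each.
#' @param var_equal pooled (TRUE) or Welch (FALSE).
#' @param degenerate_tol equality tolerance (mm) for rays where both
#'   samples are constant.
#' @return Numeric vector of two-sided p-values with a logical `degenerate`
#'   attribute flagging zero-variance rays.
#' @export
ttest_rows <- function(m1, m2, var_equal = TRUE, degenerate_tol = 0.1) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  stopifnot(nrow(m1) == nrow(m2), ncol(m1) >= 2L, ncol(m2) >= 2L)
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((m2 - mu2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (mu1 - mu2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  deg <- se == 0 | !is.finite(se)
  if (any(deg)) {
    eq <- abs(mu1 - mu2) <= degenerate_tol
    p[deg & eq] <- 1
    p[deg & !eq] <- 0
  }
  structure(p, degenerate = deg)
}

#' Evaluate contour propagation against interobserver variability
#'
#' Runs the per-ray two-tailed Student's t-test on all rays of the fan —
#' each population one set of (typically five) per-observer distances from
#' the shared CMP — and summarizes the propagated-contour deviations from
#' the manual mean surface in the per-axis layout.
#'
#' No multiple-testing correction is applied (by design); at alpha = 0.05
#' about `0.05 * n_rays` rays are expected below threshold under the null,
#' which is recorded in the result for captioning.
#'
#' @param manual rays x observers distance matrix of the manual population
#'   (from \code{\link{observer_distance_matrix}}).
#' @param propagated rays x observers distance matrix of the propagated
#'   population, measured from the same CMP on the same fan.
#' @param fan the shared `ray_fan`.
#' @param alpha significance threshold (default 0.05; p < alpha flags
#'   propagation failure on that ray).
#' @param var_equal pooled-variance Student form (default) or Welch.
#' @return A `p_value_surface`: list with `p` (per-ray p-values), `alpha`,
#'   `pass` (p >= alpha), `pass_fraction`, `expected_false_flags`,
#'   `deviation_summary` (12-column layout of propagated-vs-manual-mean
#'   deviations) and `table` (per-ray data.frame).
#' @export
evaluate_propagation <- function(manual, propagated, fan, alpha = 0.05,
                                 var_equal = TRUE) {
  manual <- as.matrix(manual); propagated <- as.matrix(propagated)
  n <- nrow(fan$directions)
  if (nrow(manual) != n || nrow(propagated) != n)
    stop("distance matrices must cover every ray of the fan")
  if (anyNA(manual) || anyNA(propagated)) stop("missing observers or rays")
  p <- ttest_rows(manual, propagated, var_equal = var_equal)
  pass <- p >= alpha
  # propagated deviations from the manual mean surface, per-axis layout
  mu_manual <- rowMeans(manual)
  dev <- propagated - mu_manual
  axis_abs <- array(0, c(n, ncol(propagated), 3))
  for (k in 1:3) axis_abs[, , k] <- abs(dev * fan$directions[, k])
  rst <- structure(list(
    table = data.frame(ray = seq_len(n), elevation_deg = fan$elevation_deg,
                       azimuth_deg = fan$azimuth_deg,
                       mean_mm = rowMeans(propagated),
                       sd_mm = apply(propagated, 1, stats::sd)),
    distances = propagated, deviations = dev, axis_abs = axis_abs, fan = fan),
    class = "radial_sample_table")
  structure(list(p = as.numeric(p), alpha = alpha, pass = pass,
                 pass_fraction = mean(pass),
                 n_tests = n,
                 degenerate = attr(p, "degenerate"),
                 expected_false_flags = alpha * n,
                 deviation_summary = global_summary(rst),
                 sample_table = rst,
                 table = data.frame(ray = seq_len(n),
                                    elevation_deg = fan$elevation_deg,
                                    azimuth_deg = fan$azimuth_deg,
                                    p = as.numeric(p), pass = pass)),
            class = "p_value_surface")
}

#' @export
print.p_value_surface <- function(x, ...) {
  cat("<p_value_surface>", x$n_tests, "per-ray tests; pass fraction (p >= ",
      x$alpha, ") = ", signif(x$pass_fraction, 4), "\n", sep = "")
  invisible(x)
}

#' Compare intraobserver variability with propagated variability
#'
#' Per ray: the intraobserver spread — the standard deviation over
#' observers of the difference between their two contouring passes of the
#' same image — against the propagated spread, the standard deviation over
#' observers of the difference between their propagated planning contour
#' and their first-pass contour. The binary map marks rays where the
#' intraobserver spread is smaller than the propagated spread; a two-sided
#' variance-ratio (F) p-value is reported alongside as a descriptive aid.
#'
#' @param first_pass rays x observers distances, first contouring session.
#' @param second_pass rays x observers distances, repeat session (same
#'   observers, same image).
#' @param propagated rays x observers distances of each observer's
#'   propagated contour, same fan.
#' @return A data.frame per ray: `intra_sd`, `prop_sd`, `intra_smaller`,
#'   `p_var` (F-test), plus a `flag_fraction` attribute.
#' @export
intraobserver_comparison <- function(first_pass, second_pass, propagated) {
  first_pass <- as.matrix(first_pass)
  if (is.null(second_pass))
    stop("intraobserver comparison needs a second contouring pass")
  second_pass <- as.matrix(second_pass); propagated <- as.matrix(propagated)
  stopifnot(nrow(first_pass) == nrow(second_pass),
            nrow(first_pass) == nrow(propagated),
            ncol(first_pass) == ncol(second_pass))
  d_intra <- second_pass - first_pass
  d_prop <- propagated - first_pass
  sd_rows <- function(m) {
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  }
  intra_sd <- sd_rows(d_intra)
  prop_sd <- sd_rows(d_prop)
  f <- (prop_sd^2) / pmax(intra_sd^2, .Machine$double.xmin)
  df1 <- ncol(propagated) - 1L; df2 <- ncol(first_pass) - 1L
  p_var <- 2 * pmin(stats::pf(f, df1, df2), 1 - stats::pf(f, df1, df2))
  out <- data.frame(ray = seq_len(nrow(first_pass)),
                    intra_sd = intra_sd, prop_sd = prop_sd,
                    intra_smaller = intra_sd < prop_sd,
                    p_var = p_var)
  attr(out, "flag_fraction") <- mean(out$intra_smaller)
  out
}

#' Summarize an experiment across propagation designs
#'
#' Three-row summary (manual interobserver, affine propagation, elastic
#' propagation) in the per-axis mean/std/max layout, plus per-design
#' box-plot statistics (median, quartiles, extremes) of the absolute 3D
#' deviations.
#'
#' @param manual_tables list of `radial_sample_table` for the manual
#'   populations (one per evaluated image).
#' @param affine_evals,elastic_evals lists of `p_value_surface` from
#'   \code{\link{evaluate_propagation}} for the two registration modes.
#' @return A list with `summary` (3 x 12 matrix, rows Segment/Affine/
#'   Elastic), `boxplot` (data.frame of five-number summaries) and
#'   `pass_fractions`.
#' @export
summarize_experiment <- function(manual_tables, affine_evals, elastic_evals) {
  stopifnot(length(affine_evals) >= 1L, length(elastic_evals) >= 1L)
  row_seg <- global_summary(manual_tables)
  row_aff <- pooled_eval_summary(affine_evals)
  row_ela <- pooled_eval_summary(elastic_evals)
  summary <- rbind(Segment = row_seg, Affine = row_aff, Elastic = row_ela)
  bx <- do.call(rbind, list(
    boxstats("Segment", unlist(lapply(manual_tables, function(t) abs(t$deviations)))),
    boxstats("Affine", unlist(lapply(affine_evals, function(e) abs(e$sample_table$deviations)))),
    boxstats("Elastic", unlist(lapply(elastic_evals, function(e) abs(e$sample_table$deviations))))))
  list(summary = summary,
       boxplot = bx,
       pass_fractions = data.frame(
         mode = rep(c("affine", "elastic"),
                    c(length(affine_evals), length(elastic_evals))),
         design = c(seq_along(affine_evals), seq_along(elastic_evals)),
         pass_fraction = c(vapply(affine_evals, `[[`, numeric(1), "pass_fraction"),
                           vapply(elastic_evals, `[[`, numeric(1), "pass_fraction"))))
}

pooled_eval_summary <- function(evals) {
  global_summary(lapply(evals, `[[`, "sample_table"))
}

boxstats <- function(label, v) {
  q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  data.frame(population = label, min = q[1], q1 = q[2], median = q[3],
             q3 = q[4], max = q[5])
}
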