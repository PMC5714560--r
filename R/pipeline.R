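#' Build a star-shaped surface mesh directly from a radial surface
#'
#' Samples the radial function on an (elevation, azimuth) grid (elevation at
#' midpoints of equal bins, poles capped with apex vertices) and returns a
#' closed, consistently oriented triangle mesh.
#'
#' @param surface a `radial_surface`.
#' @param n_elev elevation rings.
#' @param n_azim azimuth samples per ring.
#' @return A `surface_mesh`.
#' @export
surface_to_mesh <- function(surface, n_elev = 48L, n_azim = 64L) {
  stopifnot(inherits(surface, "radial_surface"))
  th <- (seq_len(n_elev) - 0.5) / n_elev * pi
  ph <- (seq_len(n_azim) - 1) / n_azim * 2 * pi
  g <- expand.grid(phi = ph, theta = th)
  d <- sph_dir(g$theta, g$phi)
  r <- surface$radius(g$theta, g$phi)
  verts <- sweep(d * r, 2, surface$center, "+")
  vtop <- surface$center + c(0, 0, surface$radius(0, 0))
  vbot <- surface$center + c(0, 0, -surface$radius(pi, 0))
  # note: theta = 0 is the +y pole
  verts <- rbind(verts, vtop, vbot)
  itop <- nrow(verts) - 1L; ibot <- nrow(verts)
  tri <- list()
  j <- seq_len(n_azim); jn <- c(2:n_azim, 1L)
  for (i in seq_len(n_elev - 1L)) {
    b0 <- (i - 1L) * n_azim
    tri[[length(tri) + 1L]] <- cbind(b0 + j, b0 + n_azim + j, b0 + jn)
    tri[[length(tri) + 1L]] <- cbind(b0 + jn, b0 + n_azim + j, b0 + n_azim + jn)
  }
  tri[[length(tri) + 1L]] <- cbind(itop, j, jn)          # theta ~ 0 ring
  bl <- (n_elev - 1L) * n_azim
  tri[[length(tri) + 1L]] <- cbind(ibot, bl + jn, bl + j)
  mesh <- new_surface_mesh(unname(as.matrix(verts)), do.call(rbind, tri))
  if (mesh_volume(mesh) < 0) mesh$triangles <- mesh$triangles[, c(1, 3, 2)]
  mesh
}

#' Experiment configuration
#'
#' Full study configuration: phantom, fraction schedule with ground-truth
#' deformations, observer model, registration settings and evaluation
#' thresholds, all driven by one master seed through named substreams. The
#' default mirrors the serial-CT study design: one planning CT plus three
#' follow-up CTs for each of two synthetic patients (the second with finer
#' 0.8301 mm in-plane pixels), five observers, and a repeat contouring pass
#' for the intraobserver arm.
#'
#' @param n_patients synthetic patients (default 2).
#' @param n_fractions follow-up CTs per patient (default 3).
#' @param phantom named list of \code{\link{phantom_spec}} overrides.
#' @param observers named list of \code{\link{observer_model}} overrides.
#' @param registration named list of \code{\link{registration_config}}
#'   overrides.
#' @param deformation list: `translation_sd_mm`, `rotation_sd_deg`,
#'   `scale_sd`, `elastic_amplitude_mm`, `elastic_spacing_mm` controlling
#'   the per-fraction ground-truth deformations.
#' @param alpha per-ray significance threshold (default 0.05).
#' @param n_contour_points contour points per simulated slice polygon.
#' @param intra_arm simulate the repeat contouring pass and run the
#'   intraobserver comparison (default TRUE).
#' @param seed master seed.
#' @param output_dir optional directory for report files.
#' @return An `experiment_config` (a plain named list; round-trips through
#'   YAML losslessly).
#' @export
experiment_config <- function(n_patients = 2L,
                              n_fractions = 3L,
                              phantom = list(),
                              observers = list(),
                              registration = list(),
                              deformation = list(translation_sd_mm = 2,
                                                 rotation_sd_deg = 1.5,
                                                 scale_sd = 0.015,
                                                 elastic_amplitude_mm = 4,
                                                 elastic_spacing_mm = 25),
                              alpha = 0.05,
                              n_contour_points = 64L,
                              intra_arm = TRUE,
                              seed = 1L,
                              output_dir = NULL) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_fractions = as.integer(n_fractions),
              phantom = phantom, observers = observers,
              registration = registration,
              deformation = modifyList(
                list(translation_sd_mm = 2, rotation_sd_deg = 1.5,
                     scale_sd = 0.015, elastic_amplitude_mm = 4,
                     elastic_spacing_mm = 25), deformation),
              alpha = alpha,
              n_contour_points = as.integer(n_contour_points),
              intra_arm = isTRUE(intra_arm),
              seed = as.integer(seed),
              output_dir = output_dir)
  structure(cfg, class = c("experiment_config", "list"))
}

#' Write / read an experiment configuration as YAML
#' @param cfg an `experiment_config`.
#' @param path YAML file path.
#' @return `path` invisibly / the `experiment_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

# per-fraction ground-truth deformation drawn from the config's substreams
fraction_truth <- function(cfg, patient, fraction) {
  s <- substream_seed(cfg$seed, sprintf("truth-p%d-f%d", patient, fraction))
  set.seed(s)
  dd <- cfg$deformation
  ground_truth_deformation(
    translation_mm = rnorm(3, 0, dd$translation_sd_mm),
    rotation_deg = rnorm(3, 0, dd$rotation_sd_deg),
    scale = 1 + rnorm(3, 0, dd$scale_sd),
    shear = c(0, 0, 0),
    elastic_amplitude_mm = dd$elastic_amplitude_mm,
    elastic_spacing_mm = dd$elastic_spacing_mm,
    seed = s)
}

patient_phantom_spec <- function(cfg, patient) {
  overrides <- cfg$phantom
  # second patient uses the finer in-plane pixel size of the study design
  if (is.null(overrides$spacing_mm) && patient == 2L)
    overrides$spacing_mm <- c(0.8301, 0.8301, 5.0)
  overrides$seed <- substream_seed(cfg$seed, paste0("phantom-", patient))
  do.call(phantom_spec, overrides)
}

#' Run the full synthetic contour-propagation experiment
#'
#' End-to-end study: simulate planning and follow-up CTs with known
#' deformations, simulate five-observer prostate contours on every image
#' (plus a repeat pass for the intraobserver arm), register planning
#' (floating) to each follow-up (reference) with affine and elastic stages,
#' propagate each observer's planning contours, sample all surfaces on the
#' shared 2048-ray fan of each follow-up image and run the per-ray t-tests,
#' then pool everything into the three-row deviation summary and box-plot
#' statistics. Contours always propagate from the planning CT onto the
#' following images.
#'
#' @param cfg an \code{\link{experiment_config}}.
#' @param verbose print stage progress.
#' @return A list: `summary` (3 x 12 deviation table), `boxplot`,
#'   `pass_fractions`, `designs` (per patient/fraction evaluation objects),
#'   `intra` (per-design intraobserver comparisons, if enabled) and
#'   `manifest`. If `cfg$output_dir` is set, CSV/JSON reports are written
#'   there as well.
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  manual_tables <- list(); affine_evals <- list(); elastic_evals <- list()
  designs <- list(); intra <- list()
  for (p in seq_len(cfg$n_patients)) {
    spec <- patient_phantom_spec(cfg, p)
    say("patient %d: generating planning phantom (%s voxels)", p,
        paste(spec$grid_shape, collapse = "x"))
    planning <- generate_phantom(spec)
    obs_args <- cfg$observers
    obs_args$seed <- substream_seed(cfg$seed, paste0("observers-", p))
    obs <- do.call(observer_model, obs_args)
    slice_sp <- spec$spacing_mm[3]
    plan_slice_ys <- axis_coords(planning$volume, 3)
    plan_cs1 <- simulate_observer_contours(planning$surface, obs, slice_sp,
                                           n_points = cfg$n_contour_points,
                                           pass = 1L,
                                           image_id = paste0("plan-", p),
                                           slice_ys = plan_slice_ys)
    roi <- roi_around(do.call(rbind, lapply(plan_cs1, contour_points_3d)),
                      margin_mm = (cfg$registration$roi_margin_mm %||% 20))
    reg_args <- cfg$registration
    reg_args$seed <- substream_seed(cfg$seed, paste0("registration-", p))
    reg_cfg <- do.call(registration_config, reg_args)
    for (f in seq_len(cfg$n_fractions)) {
      key <- sprintf("p%d_f%d", p, f)
      truth <- fraction_truth(cfg, p, f)
      say("%s: deforming phantom (elastic amplitude %g mm)", key,
          truth$elastic_amplitude_mm)
      def <- deform_phantom(planning$volume, truth)
      # true follow-up prostate surface: planning truth mapped through the
      # inverse of the pull-back map
      plan_mesh <- surface_to_mesh(planning$surface)
      true_fu_mesh <- map_mesh(plan_mesh, function(v)
        if (is.null(def$transform$field) )
          apply_affine(invert_affine(def$transform$affine), v)
        else invert_transform(def$transform, v))
      slice_ys <- axis_coords(def$volume, 3)
      fu_cs1 <- simulate_observer_contours(true_fu_mesh, obs, slice_sp,
                                           n_points = cfg$n_contour_points,
                                           pass = 1L, image_id = key,
                                           slice_ys = slice_ys)
      say("%s: affine registration", key)
      aff <- register_affine(def$volume, planning$volume, roi, reg_cfg)
      say("%s: elastic registration (ncc after affine %.4f)", key,
          attr(aff, "ncc"))
      ela <- register_elastic(def$volume, planning$volume, aff, roi, reg_cfg)
      prop_aff <- lapply(plan_cs1, propagate_contours, t = cc_transform(aff),
                         slice_ys = slice_ys,
                         n_points = cfg$n_contour_points)
      prop_ela <- lapply(plan_cs1, propagate_contours, t = ela,
                         slice_ys = slice_ys,
                         n_points = cfg$n_contour_points)
      cmp <- compute_cmp(fu_cs1)
      fan <- make_ray_fan(cmp)
      manual_d <- observer_distance_matrix(fu_cs1, fan)
      aff_d <- observer_distance_matrix(prop_aff, fan)
      ela_d <- observer_distance_matrix(prop_ela, fan)
      rst <- average_surface_and_variability(manual_d, fan)
      ev_a <- evaluate_propagation(manual_d, aff_d, fan, alpha = cfg$alpha)
      ev_e <- evaluate_propagation(manual_d, ela_d, fan, alpha = cfg$alpha)
      say("%s: pass fractions affine %.3f / elastic %.3f", key,
          ev_a$pass_fraction, ev_e$pass_fraction)
      manual_tables[[key]] <- rst
      affine_evals[[key]] <- ev_a
      elastic_evals[[key]] <- ev_e
      if (cfg$intra_arm) {
          fu_cs2 <- simulate_observer_contours(true_fu_mesh, obs, slice_sp,
                                             n_points = cfg$n_contour_points,
                                             pass = 2L, image_id = key,
                                             slice_ys = slice_ys)
        d2 <- observer_distance_matrix(fu_cs2, fan)
        intra[[key]] <- intraobserver_comparison(manual_d, d2, ela_d)
      }
      designs[[key]] <- list(patient = p, fraction = f, truth = truth,
                             affine = aff, elastic = ela,
                             affine_eval = ev_a, elastic_eval = ev_e,
                             cmp = cmp)
    }
  }
  res <- summarize_experiment(manual_tables, affine_evals, elastic_evals)
  res$designs <- designs
  res$intra <- if (cfg$intra_arm) intra
  res$manual_tables <- manual_tables
  res$manifest <- list(package = "contourcast",
                       version = as.character(utils::packageVersion("contourcast")),
                       seed = cfg$seed,
                       config = unclass(cfg),
                       axes = cc_axes(), units = "mm")
  if (!is.null(cfg$output_dir)) write_experiment_report(res, cfg$output_dir)
  res
}

#' Write experiment reports (CSV/JSON) to a directory
#' @param res result of \code{\link{run_experiment}}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cbind(population = rownames(res$summary),
                         as.data.frame(res$summary)),
                   file.path(dir, "deviation_summary.csv"), row.names = FALSE)
  utils::write.csv(res$boxplot, file.path(dir, "boxplot_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(res$pass_fractions, file.path(dir, "pass_fractions.csv"),
                   row.names = FALSE)
  for (key in names(res$designs)) {
    d <- res$designs[[key]]
    utils::write.csv(d$elastic_eval$table,
                     file.path(dir, paste0("pvalues_elastic_", key, ".csv")),
                     row.names = FALSE)
    utils::write.csv(d$affine_eval$table,
                     file.path(dir, paste0("pvalues_affine_", key, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
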