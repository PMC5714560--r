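#' Normalized cross-correlation of two intensity blocks
#'
#' Pearson correlation of voxel intensities — the similarity measure for
#' same-modality CT-to-CT registration. Invariant to affine intensity
#' rescaling of either argument.
#'
#' @param a,b numeric arrays/vectors of equal length.
#' @return Scalar in `[-1, 1]`; defined as 0 (with a warning) when either
#'   block has zero variance (flat region of interest).
#' @export
ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("ncc: blocks must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("ncc: fewer than 2 overlapping samples")
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) {
    warning("ncc: zero-variance block (flat ROI); returning 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Registration configuration
#'
#' @param levels Gaussian pyramid depth (>= 1; default 3, downsampling
#'   factor 2 per level; axes with few slices are not decimated).
#' @param roi_margin_mm dilation of the planning prostate bounding box that
#'   defines the region of interest restricting the similarity (default 20).
#' @param affine_stage_iters Nelder-Mead iteration cap per affine stage.
#' @param elastic_ctrl_spacing_mm control-grid spacings for the elastic
#'   stages, coarse to fine (default 20 then 10 mm).
#' @param elastic_iters L-BFGS-B iteration cap per elastic stage.
#' @param elastic_lambda bending-regularization weight.
#' @param target_samples cap on similarity sample points per level.
#' @param tol relative convergence tolerance of the optimizers.
#' @param seed seed for any stochastic sampling (the default pipeline is
#'   fully deterministic; kept for reproducibility bookkeeping).
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(levels = 3L,
                                roi_margin_mm = 20,
                                affine_stage_iters = 250L,
                                elastic_ctrl_spacing_mm = c(20, 10),
                                elastic_iters = 50L,
                                elastic_lambda = 0.005,
                                target_samples = 30000L,
                                tol = 1e-7,
                                seed = 1L) {
  stopifnot(levels >= 1L, roi_margin_mm >= 0, all(elastic_ctrl_spacing_mm > 0),
            elastic_iters >= 1L, elastic_lambda >= 0, target_samples >= 100L)
  structure(list(levels = as.integer(levels), roi_margin_mm = roi_margin_mm,
                 affine_stage_iters = as.integer(affine_stage_iters),
                 elastic_ctrl_spacing_mm = as.numeric(elastic_ctrl_spacing_mm),
                 elastic_iters = as.integer(elastic_iters),
                 elastic_lambda = elastic_lambda,
                 target_samples = as.integer(target_samples),
                 tol = tol, seed = as.integer(seed)),
            class = "registration_config")
}

#' Region of interest around a structure
#' @param x a `contour_set`, `surface_mesh` or n x 3 point matrix.
#' @param margin_mm isotropic dilation of the bounding box.
#' @return List with `lower` and `upper` (mm).
#' @export
roi_around <- function(x, margin_mm = 20) {
  pts <- if (is_contour_set(x)) contour_points_3d(x)
  else if (inherits(x, "surface_mesh")) x$vertices
  else as.matrix(x)
  list(lower = apply(pts, 2, min) - margin_mm,
       upper = apply(pts, 2, max) + margin_mm)
}

clip_roi <- function(roi, vol) {
  b <- volume_bounds(vol)
  list(lower = pmax(roi$lower, b[1, ]), upper = pmin(roi$upper, b[2, ]))
}

# voxel-centre sample grid of `vol` restricted to the ROI, strided so the
# total count stays at or below `target`
roi_sample_grid <- function(vol, roi, target) {
  ax <- lapply(1:3, function(k) {
    cc <- axis_coords(vol, k)
    cc[cc >= roi$lower[k] & cc <= roi$upper[k]]
  })
  n <- prod(vapply(ax, length, integer(1)))
  if (n == 0) stop("ROI does not overlap the volume domain")
  stride <- 1L
  while (n / stride^2 > target) stride <- stride + 1L   # stride in-plane only
  if (stride > 1L) {
    ax[[1]] <- ax[[1]][seq(1L, length(ax[[1]]), by = stride)]
    ax[[2]] <- ax[[2]][seq(1L, length(ax[[2]]), by = stride)]
  }
  ax
}

grid_points <- function(ax) {
  as.matrix(expand.grid(x = ax[[1]], z = ax[[2]], y = ax[[3]],
                        KEEP.OUT.ATTRS = FALSE))
}

build_pyramid <- function(vol, levels) {
  out <- vector("list", levels)
  out[[1]] <- vol
  if (levels > 1) for (l in 2:levels) out[[l]] <- downsample_volume(out[[l - 1]], 2L)
  out
}

affine_from_params <- function(p, center) {
  affine_transform(translation = p[1:3], rotation_deg = p[4:6],
                   scale = 1 + 0.01 * p[7:9], shear = 0.01 * p[10:12],
                   center = center)
}

# NCC between reference samples and the floating volume through a point map
similarity_at <- function(a_ref, flt, pts_mapped) {
  b <- interp_volume(flt, pts_mapped)
  ok <- !is.na(b)
  if (sum(ok) < max(32L, 0.25 * length(b))) return(-1)   # degenerate overlap
  aa <- a_ref[ok]; bb <- b[ok]
  sa <- stats::sd(aa); sb <- stats::sd(bb)
  if (sa == 0 || sb == 0) return(0)
  stats::cor(aa, bb)
}

#' Hierarchical affine registration
#'
#' Estimates the 12-parameter affine map from the reference (fixed,
#' follow-up) image into the floating (moving, planning) image — the
#' resampling convention — by maximizing intensity cross-correlation over a
#' region of interest around the prostate, coarse-to-fine over a Gaussian
#' pyramid. At each level the parameters are optimized in three nested
#' stages (translation; + rotation and scaling; + shear) with Nelder-Mead on
#' normalized parameters. Deterministic given the configuration.
#'
#' @param reference fixed `ct_volume` (a follow-up CT).
#' @param floating moving `ct_volume` (the planning CT).
#' @param roi list(lower, upper) mm on the reference; see
#'   \code{\link{roi_around}}.
#' @param cfg a `registration_config`.
#' @param init optional initial `cc_affine`.
#' @return A `cc_affine` with attributes `ncc` (final similarity),
#'   `converged`, and `trace` (per-level similarity before/after).
#' @export
register_affine <- function(reference, floating, roi, cfg = registration_config(),
                            init = NULL) {
  stopifnot(is_ct_volume(reference), is_ct_volume(floating))
  roi <- clip_roi(roi, reference)
  center <- (roi$lower + roi$upper) / 2
  pyr <- build_pyramid(reference, cfg$levels)
  fpyr <- build_pyramid(floating, cfg$levels)
  p <- rep(0, 12)
  if (!is.null(init) && !is.null(init$params)) {
    pr <- init$params
    p <- c(pr$translation, pr$rotation_deg, 100 * (pr$scale - 1), 100 * pr$shear)
  }
  trace <- list()
  conv <- TRUE
  stages <- list(1:3, 1:9, 1:12)
  for (l in seq(cfg$levels, 1L)) {
    ref_l <- pyr[[l]]; flt_l <- fpyr[[l]]
    ax <- roi_sample_grid(ref_l, roi, cfg$target_samples)
    pts <- grid_points(ax)
    a_ref <- interp_volume(ref_l, pts)
    keep <- !is.na(a_ref)
    pts <- pts[keep, , drop = FALSE]; a_ref <- a_ref[keep]
    fn <- function(pfull) {
      t <- try(affine_from_params(pfull, center), silent = TRUE)
      if (inherits(t, "try-error")) return(1)
      -similarity_at(a_ref, flt_l, apply_affine(t, pts))
    }
    s0 <- -fn(p)
    best <- s0
    # Nelder-Mead benefits from restarts: cycle the nested stages until the
    # similarity stops improving
    for (cycle in 1:4) {
      for (st in stages) {
        obj <- function(psub) { pp <- p; pp[st] <- psub; fn(pp) }
        res <- stats::optim(p[st], obj, method = "Nelder-Mead",
                            control = list(maxit = cfg$affine_stage_iters,
                                           reltol = cfg$tol))
        p[st] <- res$par
        if (res$convergence != 0) conv <- FALSE
      }
      now <- -fn(p)
      if (now - best < 1e-6) { best <- now; break }
      best <- now
    }
    trace[[length(trace) + 1L]] <- c(level = l, ncc_init = s0, ncc_final = best)
  }
  out <- affine_from_params(p, center)
  attr(out, "ncc") <- trace[[length(trace)]][["ncc_final"]]
  attr(out, "converged") <- conv
  attr(out, "trace") <- do.call(rbind, trace)
  out
}

# padded control lattice covering the ROI
make_control_lattice <- function(roi, spacing) {
  spacing <- rep(spacing, length.out = 3)
  n_in <- pmax(ceiling((roi$upper - roi$lower) / spacing), 1) + 1
  origin <- roi$lower - spacing
  n <- n_in + 3L
  list(origin = origin, spacing = spacing, n = as.integer(n))
}

# lattice bending energy (squared second differences) and its gradient
bending_energy <- function(ctrl) {
  e <- 0; g <- array(0, dim(ctrl))
  d <- dim(ctrl)
  for (ax in 1:3) {
    if (d[ax] < 3) next
    perm <- c(ax, setdiff(1:3, ax), 4)
    a <- aperm(ctrl, perm)
    n1 <- dim(a)[1]
    d2 <- a[1:(n1 - 2), , , , drop = FALSE] - 2 * a[2:(n1 - 1), , , , drop = FALSE] +
      a[3:n1, , , , drop = FALSE]
    e <- e + sum(d2^2)
    ga <- array(0, dim(a))
    ga[1:(n1 - 2), , , ] <- ga[1:(n1 - 2), , , ] + 2 * d2
    ga[2:(n1 - 1), , , ] <- ga[2:(n1 - 1), , , ] - 4 * d2
    ga[3:n1, , , ] <- ga[3:n1, , , ] + 2 * d2
    g <- g + aperm(ga, order(perm))
  }
  nrm <- prod(dim(ctrl))
  list(value = e / nrm, grad = g / nrm)
}

# gradient volumes of a ct_volume (per mm, central differences)
gradient_volumes <- function(vol) {
  a <- vol$data; d <- dim(a)
  lapply(1:3, function(ax) {
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    ap <- aperm(a, perm)
    n1 <- dim(ap)[1]
    g <- ap
    g[2:(n1 - 1), , ] <- (ap[3:n1, , ] - ap[1:(n1 - 2), , ]) / 2
    g[1, , ] <- ap[2, , ] - ap[1, , ]
    g[n1, , ] <- ap[n1, , ] - ap[n1 - 1, , ]
    ct_volume(aperm(g, order(perm)) / vol$spacing[ax], vol$spacing, vol$origin)
  })
}

#' Elastic (B-spline) registration refining an affine initialization
#'
#' Optimizes a cubic B-spline displacement field on a control grid over the
#' region of interest, refining the affine map: the total transform is
#' `T(x) = A x + b + u(x)`. The objective is intensity cross-correlation
#' minus a bending-energy regularization of the control lattice, maximized
#' with L-BFGS-B using the analytic gradient; multiresolution both in the
#' image (pyramid level per stage) and in the control grid (coarse-to-fine
#' spacings). If the final map folds (non-positive Jacobian on the ROI) the
#' regularization weight is doubled and the finest stage re-run once; a
#' persistent fold is an error.
#'
#' @param reference fixed `ct_volume`.
#' @param floating moving `ct_volume`.
#' @param init `cc_affine` from \code{\link{register_affine}}.
#' @param roi list(lower, upper) mm on the reference.
#' @param cfg a `registration_config`.
#' @return A `cc_transform` (affine + field) with attributes `ncc`,
#'   `trace` and `lambda_used`.
#' @export
register_elastic <- function(reference, floating, init, roi,
                             cfg = registration_config()) {
  stopifnot(is_ct_volume(reference), is_ct_volume(floating),
            inherits(init, "cc_affine"))
  roi <- clip_roi(roi, reference)
  spacings <- cfg$elastic_ctrl_spacing_mm
  n_stage <- length(spacings)
  # pair control-grid stages with pyramid levels, finest stage at level 1
  levels <- rev(seq_len(n_stage))
  levels <- pmin(levels, cfg$levels)
  pyr <- build_pyramid(reference, max(levels))
  fpyr <- build_pyramid(floating, max(levels))
  grads <- lapply(fpyr, gradient_volumes)

  run_stage <- function(lat, ctrl, level, lambda) {
    ref_l <- pyr[[level]]; flt_l <- fpyr[[level]]; g_l <- grads[[level]]
    ax <- roi_sample_grid(ref_l, roi, cfg$target_samples)
    pts <- grid_points(ax)
    a_ref <- interp_volume(ref_l, pts)
    ok0 <- !is.na(a_ref)
    dims <- vapply(ax, length, integer(1))
    basis <- lapply(1:3, function(k)
      bspline_basis_matrix(ax[[k]], lat$origin[k], lat$spacing[k], lat$n[k]))
    mapped0 <- apply_affine(init, pts)
    field_of <- function(v) deformation_field(array(v, c(lat$n, 3)),
                                              lat$origin, lat$spacing)
    eval_u <- function(v) {
      fld <- array(v, c(lat$n, 3))
      do.call(cbind, lapply(1:3, function(comp) {
        a <- fld[, , , comp]; dim(a) <- lat$n
        as.numeric(tensor_apply(basis[[3]],
                                tensor_apply(basis[[2]],
                                             tensor_apply(basis[[1]], a, 1), 2), 3))
      }))
    }
    objective <- function(v) {
      u <- eval_u(v)
      b <- interp_volume(flt_l, mapped0 + u)
      ok <- ok0 & !is.na(b)
      aa <- a_ref[ok]; bb <- b[ok]
      sa <- stats::sd(aa); sb <- stats::sd(bb)
      be <- bending_energy(array(v, c(lat$n, 3)))
      s <- if (sa == 0 || sb == 0) 0 else stats::cor(aa, bb)
      -s + lambda * be$value
    }
    gradient <- function(v) {
      u <- eval_u(v)
      pm <- mapped0 + u
      b <- interp_volume(flt_l, pm)
      ok <- ok0 & !is.na(b)
      n <- sum(ok)
      aa <- a_ref[ok]; bb <- b[ok]
      a0 <- aa - mean(aa); b0 <- bb - mean(bb)
      sa <- sqrt(sum(a0^2)); sb <- sqrt(sum(b0^2))
      gpts <- matrix(0, nrow(pts), 3)
      if (sa > 0 && sb > 0) {
        s <- sum(a0 * b0) / (sa * sb)
        dncc_db <- a0 / (sa * sb) - s * b0 / sb^2
        for (k in 1:3) {
          gk <- interp_volume(g_l[[k]], pm[ok, , drop = FALSE])
          gk[is.na(gk)] <- 0
          gpts[ok, k] <- dncc_db * gk
        }
      }
      be <- bending_energy(array(v, c(lat$n, 3)))
      gctrl <- array(0, c(lat$n, 3))
      for (k in 1:3) {
        garr <- array(gpts[, k], dims)
        gctrl[, , , k] <- field_project_grid(garr, basis)
      }
      as.numeric(-gctrl) + lambda * as.numeric(be$grad)
    }
    res <- stats::optim(as.numeric(ctrl), objective, gradient,
                        method = "L-BFGS-B",
                        control = list(maxit = cfg$elastic_iters,
                                       factr = cfg$tol / .Machine$double.eps))
    obj0 <- objective(as.numeric(ctrl))
    list(ctrl = array(res$par, c(lat$n, 3)),
         ncc_init = -obj0, ncc_final = -res$value, field = field_of(res$par))
  }

  fit_once <- function(lambda) {
    trace <- list()
    fld <- NULL
    for (st in seq_len(n_stage)) {
      lat <- make_control_lattice(roi, spacings[st])
      ctrl <- array(0, c(lat$n, 3))
      if (!is.null(fld)) {
        # resample the previous (coarser) field onto the new lattice
        gx <- lat$origin[1] + (seq_len(lat$n[1]) - 1) * lat$spacing[1]
        gz <- lat$origin[2] + (seq_len(lat$n[2]) - 1) * lat$spacing[2]
        gy <- lat$origin[3] + (seq_len(lat$n[3]) - 1) * lat$spacing[3]
        lp <- grid_points(list(gx, gz, gy))
        uv <- field_eval(fld, lp)
        # seed control values with the coarse-field displacements; the cubic
        # B-spline slightly smooths this init and the optimization refines it
        for (k in 1:3) ctrl[, , , k] <- array(uv[, k], lat$n)
      }
      stg <- run_stage(lat, ctrl, levels[st], lambda)
      fld <- stg$field
      trace[[st]] <- c(stage = st, level = levels[st],
                       spacing = spacings[st],
                       ncc_init = stg$ncc_init, ncc_final = stg$ncc_final)
    }
    list(field = fld, trace = do.call(rbind, trace))
  }

  lambda <- cfg$elastic_lambda
  fit <- fit_once(lambda)
  out <- cc_transform(init, fit$field)
  mj <- min_jacobian(out, roi$lower, roi$upper)
  if (mj <= 0) {
    lambda <- lambda * 10
    fit <- fit_once(lambda)
    out <- cc_transform(init, fit$field)
    mj <- min_jacobian(out, roi$lower, roi$upper)
    if (mj <= 0)
      stop("elastic registration produced a folding map (min Jacobian ",
           signif(mj, 3), ") even after increasing regularization")
  }
  attr(out, "ncc") <- fit$trace[nrow(fit$trace), "ncc_final"]
  attr(out, "trace") <- fit$trace
  attr(out, "lambda_used") <- lambda
  attr(out, "min_jacobian") <- mj
  out
}
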