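#' Ground-truth deformation between serial acquisitions
#'
#' A known, invertible anatomical change applied to a phantom: an affine
#' part (translation, rotation, scaling, shear about the volume centre)
#' composed with a smooth elastic displacement field on a coarse control
#' grid. Control displacements are clipped at 40% of the control spacing — a
#' sufficient condition for invertibility, which is additionally verified
#' numerically when the deformation is applied.
#'
#' The elastic part models what actually deforms the gland between
#' fractions — focal pressure from rectal and bladder filling changes — as a
#' Gaussian push of scale `0.8 * elastic_spacing_mm` in a random direction
#' near the volume centre, plus mild smooth random roughness; both are
#' realized as control-grid displacements so the dense field stays a cubic
#' B-spline field. The push and roughness magnitudes are scaled so the dense
#' displacement norm never exceeds `elastic_amplitude_mm`.
#'
#' @param translation_mm,rotation_deg,scale,shear affine parameters (see
#'   \code{\link{affine_transform}}).
#' @param elastic_amplitude_mm bound on the elastic displacement magnitude
#'   (0 disables the elastic part).
#' @param elastic_spacing_mm control-grid spacing of the elastic part.
#' @param seed integer seed for the random control displacements.
#' @return An object of class `ground_truth_deformation`.
#' @export
ground_truth_deformation <- function(translation_mm = c(0, 0, 0),
                                     rotation_deg = c(0, 0, 0),
                                     scale = c(1, 1, 1),
                                     shear = c(0, 0, 0),
                                     elastic_amplitude_mm = 0,
                                     elastic_spacing_mm = 25,
                                     seed = 1L) {
  stopifnot(elastic_amplitude_mm >= 0, elastic_spacing_mm > 0)
  structure(list(translation_mm = translation_mm, rotation_deg = rotation_deg,
                 scale = scale, shear = shear,
                 elastic_amplitude_mm = elastic_amplitude_mm,
                 elastic_spacing_mm = elastic_spacing_mm,
                 seed = as.integer(seed)),
            class = "ground_truth_deformation")
}

# realize the deformation as a cc_transform on the given volume domain;
# the transform maps deformed-image coordinates to source-image coordinates
# (pull-back / resampling convention)
truth_transform <- function(truth, vol) {
  b <- volume_bounds(vol)
  center <- colMeans(b)
  aff <- affine_transform(truth$translation_mm, truth$rotation_deg,
                          truth$scale, truth$shear, center = center)
  fld <- NULL
  if (truth$elastic_amplitude_mm > 0) {
    lat <- make_control_lattice(list(lower = b[1, ], upper = b[2, ]),
                                truth$elastic_spacing_mm)
    set.seed(substream_seed(truth$seed, "truth-elastic"))
    amp <- truth$elastic_amplitude_mm
    cp <- lapply(1:3, function(k)
      lat$origin[k] + (seq_len(lat$n[k]) - 1) * lat$spacing[k])
    g <- grid_points(cp)
    # focal push at the posterior (rectal) interface: filling changes press
    # on the gland from the +z side, so the push is centred near the
    # posterior boundary where its gradient crosses the prostate surface
    bc <- center + c(runif(1, -8, 8), 14 + runif(1, 0, 8), runif(1, -8, 8))
    dirv <- rnorm(3) + c(0, -1.5, 0)   # predominantly anterior push
    dirv <- dirv / sqrt(sum(dirv^2))
    sig <- 0.7 * truth$elastic_spacing_mm
    w <- exp(-rowSums(sweep(g, 2, bc, "-")^2) / (2 * sig^2))
    ctrl <- array(0, c(lat$n, 3))
    rough_cap <- amp / 8
    for (k in 1:3) {
      rough <- pmin(pmax(rnorm(nrow(g), 0, rough_cap / 2), -rough_cap), rough_cap)
      ctrl[, , , k] <- array(0.78 * amp * w * dirv[k] + rough, lat$n)
    }
    # invertibility margin: clip at 40% of the control spacing
    cap <- 0.4 * min(lat$spacing)
    ctrl <- pmin(pmax(ctrl, -cap), cap)
    fld <- deformation_field(ctrl, lat$origin, lat$spacing)
  }
  cc_transform(aff, fld)
}

#' Apply a ground-truth deformation to a phantom volume
#'
#' Resamples the volume through the deformation (pull-back: the output at x
#' is the input at T(x)) and returns the exact dense displacement map used,
#' for later recovery scoring. The map is checked for invertibility
#' (positive Jacobian determinant on the domain) before resampling.
#'
#' @param vol a `ct_volume`.
#' @param truth a `ground_truth_deformation`.
#' @param outside intensity used where T(x) leaves the input domain.
#' @return A list: `volume` (deformed `ct_volume`), `transform` (the
#'   `cc_transform` T mapping deformed coordinates to source coordinates)
#'   and `displacement` (n_voxel x 3 matrix of T(x) - x, mm, in array
#'   order).
#' @export
deform_phantom <- function(vol, truth, outside = -1000) {
  stopifnot(is_ct_volume(vol), inherits(truth, "ground_truth_deformation"))
  t <- truth_transform(truth, vol)
  b <- volume_bounds(vol)
  mj <- min_jacobian(t, b[1, ], b[2, ], n = 9L)
  if (mj <= 0)
    stop("ground-truth deformation is not invertible on the volume domain ",
         "(min Jacobian ", signif(mj, 3), ")")
  d <- dim(vol$data)
  pts <- grid_points(list(axis_coords(vol, 1), axis_coords(vol, 2),
                          axis_coords(vol, 3)))
  mapped <- apply_transform(t, pts)
  vals <- interp_volume(vol, mapped, outside = outside)
  list(volume = ct_volume(array(vals, d), vol$spacing, vol$origin),
       transform = t,
       displacement = mapped - pts)
}

#' Write a dense displacement field with a JSON sidecar
#'
#' Plain-text container: displacements as CSV (one row per voxel in array
#' order, columns ux, uz, uy in mm) plus a JSON sidecar holding grid shape,
#' spacing, origin, axis convention and seed.
#'
#' @param displacement n x 3 displacement matrix (mm).
#' @param vol the `ct_volume` whose grid the field lives on.
#' @param path output path stem; writes `<path>.csv` and `<path>.json`.
#' @param seed seed recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_displacement_field <- function(displacement, vol, path, seed = NA) {
  utils::write.csv(as.data.frame(`colnames<-`(displacement, c("ux", "uz", "uy"))),
                   paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(format = "contourcast-field", axes = cc_axes(),
                            units = "mm", grid_shape = dim(vol$data),
                            spacing = vol$spacing, origin = vol$origin,
                            seed = seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, ".json"))
}
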