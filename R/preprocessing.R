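# Beam's-eye-view preprocessing: per-beam 3D dose -> normalized 2D dose map
# (model input), and MLC control points -> MU-weighted aperture stack
# (model target).

#' Extract the dose of a single beam from a set of per-beam doses
#'
#' @param rtdose_set A named list of [dose3d()] objects (e.g. the `beams`
#'   element of [forward_dose_3d()], or doses read from disk).
#' @param beam_ref Name of the requested beam.
#' @return The beam's `dose3d`.
#' @export
extract_beam_dose <- function(rtdose_set, beam_ref) {
  if (!beam_ref %in% names(rtdose_set)) {
    stop(sprintf("no dose for beam '%s'; available: %s", beam_ref,
                 paste(names(rtdose_set), collapse = ", ")))
  }
  rtdose_set[[beam_ref]]
}

#' Resample a dose volume onto a planning grid
#'
#' Trilinear interpolation in world coordinates; voxels outside the source
#' extent are set to zero.
#' @param dose A [dose3d()].
#' @param target_grid A [grid_spec()].
#' @return A `dose3d` on `target_grid`.
#' @export
resample_to_planning_grid <- function(dose, target_grid) {
  s <- dose$grid
  s_lo <- s$origin; s_hi <- s$origin + (s$dim - 1) * s$spacing
  t_lo <- target_grid$origin
  t_hi <- target_grid$origin + (target_grid$dim - 1) * target_grid$spacing
  if (any(t_hi < s_lo) || any(t_lo > s_hi)) {
    stop("source and target grids have disjoint extents")
  }
  # identity affine in world coordinates: center choice is irrelevant
  resample_affine(dose, target_grid, R = diag(3), center = c(0, 0, 0))
}

#' Shift a dose volume so the isocenter sits at the grid rotation center
#'
#' The rotation center is the middle of the grid (index `(dim - 1) / 2`).
#' Integer-voxel shifts are exact array rolls with zero fill; sub-voxel shifts
#' use trilinear interpolation.
#' @param dose A [dose3d()].
#' @param isocenter World coordinates (mm) of the isocenter.
#' @return A shifted `dose3d` on the same grid.
#' @export
shift_to_isocenter <- function(dose, isocenter) {
  g <- dose$grid
  lo <- g$origin; hi <- g$origin + (g$dim - 1) * g$spacing
  if (any(isocenter < lo) || any(isocenter > hi)) {
    stop("isocenter outside the dose grid")
  }
  center <- g$origin + (g$dim - 1) * g$spacing / 2
  # out(p) = src(p + (iso - center)): pull-back shift
  resample_affine(dose, g, R = diag(3), shift = isocenter - center,
                  center = c(0, 0, 0))
}

#' Rotate an isocenter-centered dose volume to the beam's eye view
#'
#' Rotates by the gantry angle about the superior-inferior axis through the
#' grid center so the beam axis aligns with grid axis 2; summing along that
#' axis then yields the BEV map. Trilinear interpolation, zero fill; multiples
#' of 90 degrees are exact.
#' @param dose A [dose3d()] centered on the isocenter.
#' @param gantry_angle Gantry angle, degrees.
#' @return A rotated `dose3d`.
#' @export
rotate_to_bev <- function(dose, gantry_angle) {
  # out(q) = src(R(-g) q) about the grid center: the beam-frame point q maps
  # back to the patient-frame point it came from
  resample_affine(dose, dose$grid, R = rot_z(-gantry_angle))
}

#' Sum a BEV-aligned dose along the beam axis
#'
#' @param dose A BEV-aligned [dose3d()] (beam axis = grid axis 2).
#' @return A matrix (rows along linac X, cols along linac Y / patient SI).
#' @export
project_bev <- function(dose) {
  colSums(aperm(dose$values, c(2, 1, 3)))
}

#' Normalize and resample a 2D dose map to the model input raster
#'
#' Bilinear resampling to `size x size`, then division by the maximum; the
#' removed maximum is kept as `scale` so absolute dose can be restored. An
#' all-zero map stays zero with `scale = 0`.
#' @param map_2d Non-negative numeric matrix.
#' @param size Output raster size (default 128).
#' @param beam_ref Optional beam identifier carried along.
#' @return A `dose_map2d`: `pixels` in `[0, 1]`, `scale`, `beam_ref`.
#' @export
normalize_resample <- function(map_2d, size = 128, beam_ref = NULL) {
  if (any(map_2d < 0)) stop("dose map has negative values")
  px <- resample2d_extent(map_2d, c(0, 1), c(0, 1), size, size,
                          c(0, 1), c(0, 1), edge = "clamp")
  mx <- max(px)
  if (mx > 0) px <- px / mx
  structure(list(pixels = px, scale = mx, beam_ref = beam_ref),
            class = "dose_map2d")
}

#' Reconstruct the MU-weighted aperture stack of a beam
#'
#' Rasterizes each segment's leaf openings as a binary mask on the machine
#' field raster (ones in the open field, zeros under the leaves), multiplies
#' by the segment's normalized MU weight, orders channels by delivery order,
#' and zero-pads to 6 channels.
#'
#' @param beam A beam (gantry angle, ordered segments).
#' @param machine A [machine_model()].
#' @param size Raster size per side (default 128).
#' @param mu_scale Normalization constant for MU weights (e.g. the maximum
#'   segment MU of the plan). Defaults to the beam's maximum segment MU.
#' @param overflow What to do with beams of more than 6 segments: `"error"`
#'   (default) or `"merge"`, which repeatedly merges the two smallest-MU
#'   segments (union of openings, summed MU) until 6 remain.
#' @param extent_x,extent_y Physical extents of the raster (mm at isocenter,
#'   along linac X and Y). Default: the full machine field. Training pairs
#'   use the planning-grid extents instead, so apertures are resolved at the
#'   same scale as the BEV dose map.
#' @return An `aperture_stack`: `channels` array `[size, size, 6]`,
#'   `mu_scale`, `n_real_segments`, raster extents.
#' @export
segments_from_controlpoints <- function(beam, machine, size = 128,
                                        mu_scale = NULL,
                                        overflow = c("error", "merge"),
                                        extent_x = NULL, extent_y = NULL) {
  overflow <- match.arg(overflow)
  if (is.null(extent_x)) extent_x <- c(-1, 1) * machine$field_x_extent / 2
  if (is.null(extent_y)) extent_y <- c(-1, 1) * machine$field_y_extent / 2
  segs <- beam$segments
  if (length(segs) == 0) stop("beam has no segments")
  for (s in segs) {
    if (!any(!is.na(s$intervals[, 1]))) {
      stop("fully closed segment violates the open-plan invariant")
    }
  }
  if (length(segs) > 6) {
    if (overflow == "error") {
      stop(sprintf("beam has %d segments but the stack has 6 channels; %s",
                   length(segs), "use overflow = 'merge' to merge"))
    }
    while (length(segs) > 6) {
      mus <- vapply(segs, function(s) s$mu, 1)
      o <- order(mus)[1:2]
      a <- segs[[o[1]]]; b <- segs[[o[2]]]
      iv <- a$intervals
      iv[, 1] <- pmin(iv[, 1], b$intervals[, 1], na.rm = TRUE)
      iv[, 2] <- pmax(iv[, 2], b$intervals[, 2], na.rm = TRUE)
      iv[is.infinite(iv)] <- NA
      merged <- new_segment(iv, a$mu + b$mu)
      segs <- c(segs[-o], list(merged))
    }
  }
  if (is.null(mu_scale)) mu_scale <- max(vapply(segs, function(s) s$mu, 1))
  xs <- extent_x[1] + (seq_len(size) - 0.5) * diff(extent_x) / size
  ys <- extent_y[1] + (seq_len(size) - 0.5) * diff(extent_y) / size
  channels <- array(0, c(size, size, 6))
  for (i in seq_along(segs)) {
    channels[, , i] <- rasterize_segment(segs[[i]], machine, xs, ys) *
      (segs[[i]]$mu / mu_scale)
  }
  structure(list(channels = channels, mu_scale = mu_scale,
                 n_real_segments = length(segs),
                 gantry = beam$gantry,
                 extent_x = extent_x, extent_y = extent_y),
            class = "aperture_stack")
}

#' @export
print.aperture_stack <- function(x, ...) {
  cat(sprintf("<aperture_stack> %dx%dx6, %d real segments, mu_scale %.3g\n",
              dim(x$channels)[1], dim(x$channels)[2], x$n_real_segments,
              x$mu_scale))
  invisible(x)
}

#' Build training pairs from a synthetic cohort
#'
#' For every beam of every plan: the input is the normalized BEV dose map of
#' the beam (computed in the beam frame by the idealized engine) and the
#' target is the MU-weighted, zero-padded aperture stack. Both images live
#' on the same isocenter-centered raster spanning the planning grid's BEV
#' extents, so the network sees spatially registered pairs at the
#' planning-image scale.
#'
#' @param cohort A [sample_cohort()].
#' @param size Raster size per side.
#' @param mu_attenuation,sigma Dose engine parameters.
#' @param mu_scale MU normalization constant shared by the whole dataset
#'   (so channel intensities carry absolute MU information and predicted MU
#'   needs no plan-specific rescaling). Default: the cohort's maximum
#'   segment MU.
#' @param progress Print progress.
#' @return A `pair_set`: list of pairs (`x` matrix, `y` array, `meta`), a
#'   metadata data.frame, the shared `mu_scale` and raster extents.
#' @export
build_training_pairs <- function(cohort, size = 128, mu_attenuation = 0.005,
                                 sigma = 3, mu_scale = NULL,
                                 progress = FALSE) {
  if (is.null(mu_scale)) {
    mu_scale <- max(vapply(cohort$patients, function(pat)
      max(vapply(pat$plans, function(plan)
        max(vapply(plan$beams, function(b)
          max(vapply(b$segments, function(s) s$mu, 1)), 1)), 1)), 1))
  }
  pairs <- list()
  meta <- list()
  n <- 0L
  ext_x <- ext_y <- NULL
  for (pat in cohort$patients) {
    for (plan in pat$plans) {
      for (b in seq_along(plan$beams)) {
        beam <- plan$beams[[b]]
        bev <- beam_bev_map(beam, pat$phantom, cohort$machine,
                            mu_attenuation, sigma, size, raster = "grid")
        ext_x <- attr(bev, "extent_x")
        ext_y <- attr(bev, "extent_y")
        x <- normalize_resample(bev, size, beam_ref = sprintf("beam%02d", b))
        y <- segments_from_controlpoints(beam, cohort$machine, size,
                                         mu_scale = mu_scale,
                                         extent_x = ext_x,
                                         extent_y = ext_y)
        n <- n + 1L
        pairs[[n]] <- list(x = x$pixels, y = y$channels,
                           meta = list(patient_id = plan$patient_id,
                                       fraction = plan$fraction,
                                       beam = b, gantry = beam$gantry,
                                       scale = x$scale, mu_scale = mu_scale,
                                       n_real_segments = y$n_real_segments))
        meta[[n]] <- as.data.frame(pairs[[n]]$meta)
      }
      if (progress) message(sprintf("paired %s fx%d", plan$patient_id,
                                    plan$fraction))
    }
  }
  structure(list(pairs = pairs, meta = do.call(rbind, meta), size = size,
                 mu_scale = mu_scale, extent_x = ext_x, extent_y = ext_y),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d beam pairs at %dx%d\n", length(x$pairs),
              x$size, x$size))
  invisible(x)
}
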