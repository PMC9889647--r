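# Plan quality metrics: gamma analysis (optimized search + exhaustive
# oracle), dose-volume histograms, and per-ROI dose metric differences.

#' Gamma analysis acceptance criteria
#'
#' @param dose_tolerance Dose-difference tolerance as a fraction of the
#'   normalization dose (default 0.03 = 3 percent).
#' @param distance_tolerance Distance-to-agreement tolerance, mm (default 3).
#' @param low_dose_threshold Voxels below this fraction of the reference
#'   maximum are excluded (default 0.05 = 5 percent threshold).
#' @param normalization `"global"` (dose differences normalized to the
#'   reference maximum, the common clinical default) or `"local"`.
#' @export
gamma_criteria <- function(dose_tolerance = 0.03, distance_tolerance = 3,
                           low_dose_threshold = 0.05,
                           normalization = c("global", "local")) {
  stopifnot(dose_tolerance > 0, distance_tolerance > 0,
            low_dose_threshold > 0)
  list(dose_tolerance = dose_tolerance,
       distance_tolerance = distance_tolerance,
       low_dose_threshold = low_dose_threshold,
       normalization = match.arg(normalization))
}

#' Gamma index between a reference and an evaluated dose
#'
#' Per-voxel gamma combines the dose difference (normalized to
#' `dose_tolerance` of the reference maximum) with the distance to the
#' nearest agreeing point (normalized to `distance_tolerance`), minimized
#' over a sub-voxel-sampled neighborhood. Gamma is asymmetric: the reference
#' is the ground-truth/target dose and its voxels define the evaluation set.
#'
#' The default search enumerates offsets within `search_factor` times the
#' distance tolerance at `step_fraction` of a voxel, sorted by distance and
#' pruned exactly; `method = "brute"` runs the exhaustive unpruned search
#' used as the correctness oracle on small grids.
#'
#' @param reference,evaluated [dose3d()] objects on the same grid.
#' @param criteria A [gamma_criteria()].
#' @param search_factor Search radius in multiples of the distance tolerance.
#' @param step_fraction Offset lattice pitch as a fraction of the voxel size.
#' @param cap Optional upper bound on reported gamma values (speeds up
#'   failing voxels; any `cap` > 1 leaves the pass/fail classification
#'   unchanged). `Inf` disables capping.
#' @param method `"optimized"` or `"brute"`.
#' @return A `gamma_result`: `gamma` array (NA below the dose threshold),
#'   `pass_rate` (percent of evaluated voxels with gamma <= 1),
#'   `n_evaluated`, and the criteria.
#' @export
gamma_index <- function(reference, evaluated, criteria = gamma_criteria(),
                        search_factor = 3, step_fraction = 0.1, cap = Inf,
                        method = c("optimized", "brute")) {
  method <- match.arg(method)
  if (!all(reference$grid$dim == evaluated$grid$dim) ||
      !all(abs(reference$grid$spacing - evaluated$grid$spacing) < 1e-9)) {
    stop("reference and evaluated doses are on different grids; resample first")
  }
  dmax <- max(reference$values)
  if (dmax <= 0) stop("reference dose is empty")
  if (criteria$normalization == "local") {
    stop("local gamma normalization is not implemented; use global")
  }
  tol_abs <- criteria$dose_tolerance * dmax
  g <- reference$grid
  radius <- search_factor * criteria$distance_tolerance
  step <- step_fraction * g$spacing
  if (method == "optimized") {
    gam <- cpp_gamma_search(reference$values, evaluated$values, g$dim,
                            g$spacing, tol_abs,
                            criteria$distance_tolerance,
                            criteria$low_dose_threshold * dmax,
                            radius, step, cap)
  } else {
    gam <- cpp_gamma_bruteforce(reference$values, evaluated$values, g$dim,
                                g$spacing, tol_abs,
                                criteria$distance_tolerance,
                                criteria$low_dose_threshold * dmax,
                                radius, step)
  }
  gam <- array(gam, g$dim)
  n_eval <- sum(!is.na(gam))
  pass <- 100 * sum(gam <= 1, na.rm = TRUE) / max(n_eval, 1)
  structure(list(gamma = gam, pass_rate = pass, n_evaluated = n_eval,
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.1f%% passing (%.0f%%/%g mm, %d voxels >= %g%% of max)\n",
    x$pass_rate, 100 * x$criteria$dose_tolerance,
    x$criteria$distance_tolerance, x$n_evaluated,
    100 * x$criteria$low_dose_threshold))
  invisible(x)
}

#' Cumulative dose-volume histogram of an ROI
#'
#' @param dose A [dose3d()].
#' @param roi_mask Logical array on the same grid.
#' @param roi Name of the ROI.
#' @param bin_width Histogram bin width (cGy-equivalent dose units).
#' @return A `dvh_curve`: dose grid, cumulative volume fraction (percent),
#'   `dmax`, `dmean`, and `v(d)` lookup.
#' @export
dvh <- function(dose, roi_mask, roi = "ROI", bin_width = 1) {
  if (!all(dim(roi_mask) == dose$grid$dim)) stop("mask grid mismatch")
  vox <- dose$values[roi_mask]
  if (length(vox) == 0) stop(sprintf("ROI '%s' mask is empty", roi))
  dmax <- max(vox)
  edges <- seq(0, dmax + bin_width, by = bin_width)
  vol <- vapply(edges, function(d) 100 * mean(vox >= d), 1)
  structure(list(roi = roi, dose = edges, volume = vol,
                 dmax = dmax, dmean = mean(vox),
                 v = function(d) 100 * mean(vox >= d)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: Dmax %.1f, Dmean %.1f\n", x$roi, x$dmax,
              x$dmean))
  invisible(x)
}

#' Percent difference of a DVH summary metric (ground truth minus predicted)
#'
#' `100 * (metric_gt - metric_pred) / metric_gt`; negative values mean the
#' predicted plan exceeds the ground truth.
#' @param gt,pred `dvh_curve`s of the same ROI.
#' @param metric `"dmax"` or `"dmean"`.
#' @return Percent difference (scalar).
#' @export
dose_metric_pct_diff <- function(gt, pred, metric = c("dmax", "dmean")) {
  metric <- match.arg(metric)
  if (!identical(gt$roi, pred$roi)) {
    stop(sprintf("curves are for different ROIs (%s vs %s)", gt$roi,
                 pred$roi))
  }
  m_gt <- gt[[metric]]
  m_pred <- pred[[metric]]
  if (m_gt == 0) {
    warning("ground-truth metric is zero; percent difference undefined")
    return(NA_real_)
  }
  100 * (m_gt - m_pred) / m_gt
}

#' Evaluate a predicted plan against its ground truth
#'
#' Recomputes both doses with the same idealized engine, runs the gamma
#' analysis (ground truth as reference) and tabulates per-ROI Dmax/Dmean and
#' their percent differences for the PTV and every OAR.
#'
#' @param pred_plan The sequenced predicted plan.
#' @param gt_plan The ground-truth plan.
#' @param phantom The shared phantom.
#' @param machine A [machine_model()].
#' @param criteria A [gamma_criteria()].
#' @param mu_attenuation,sigma Dose engine parameters (shared by both plans).
#' @param gamma_cap Cap passed to [gamma_index()].
#' @return List with `gamma` (a `gamma_result`) and `metrics` (one row per
#'   ROI: Dmax/Dmean for both plans and percent differences).
#' @export
evaluate_predicted_plan <- function(pred_plan, gt_plan, phantom, machine,
                                    criteria = gamma_criteria(),
                                    mu_attenuation = 0.005, sigma = 3,
                                    gamma_cap = Inf,
                                    gamma_step_fraction = 0.1) {
  if (length(pred_plan$beams) != length(gt_plan$beams)) {
    stop("plans have different beam counts")
  }
  ang <- function(p) vapply(p$beams, function(b) b$gantry, 1)
  if (!all(ang(pred_plan) == ang(gt_plan))) {
    stop("plans have different gantry angles")
  }
  d_gt <- forward_dose_3d(gt_plan, phantom, machine, mu_attenuation, sigma,
                          per_beam = FALSE)$total
  d_pred <- forward_dose_3d(pred_plan, phantom, machine, mu_attenuation,
                            sigma, per_beam = FALSE)$total
  gam <- gamma_index(d_gt, d_pred, criteria, cap = gamma_cap,
                     step_fraction = gamma_step_fraction)
  rois <- c(list(PTV = phantom$ptv), phantom$oars)
  rows <- lapply(names(rois), function(nm) {
    c_gt <- dvh(d_gt, rois[[nm]], roi = nm)
    c_pr <- dvh(d_pred, rois[[nm]], roi = nm)
    data.frame(roi = nm,
               dmax_gt = c_gt$dmax, dmax_pred = c_pr$dmax,
               dmax_pct_diff = dose_metric_pct_diff(c_gt, c_pr, "dmax"),
               dmean_gt = c_gt$dmean, dmean_pred = c_pr$dmean,
               dmean_pct_diff = dose_metric_pct_diff(c_gt, c_pr, "dmean"))
  })
  list(gamma = gam, metrics = do.call(rbind, rows))
}
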