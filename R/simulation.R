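#' @useDynLib leafseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm
NULL

#' The fixed 11-beam gantry angle set (degrees, IEC scale)
#' @export
FIXED_GANTRY_ANGLES <- c(5, 25, 60, 90, 155, 175, 195, 260, 290, 310, 345)

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and a tag
#'
#' One global seed fans out deterministically to every stage and sample of a
#' run; derived seeds stay below 2^31.
#' @param seed Integer master seed.
#' @param ... Tags (strings/numbers) identifying the consumer.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Segment sampler configuration
#'
#' @param min_opening Smallest leaf opening generated (mm).
#' @param mu_range Monitor-unit weight range; weights are drawn log-uniformly.
#' @param shape_jitter Relative magnitude of the smooth per-row edge noise.
#' @export
segment_config <- function(min_opening = 6, mu_range = c(20, 200),
                           shape_jitter = 0.2) {
  stopifnot(min_opening > 0, length(mu_range) == 2, all(mu_range > 0))
  list(min_opening = min_opening, mu_range = mu_range,
       shape_jitter = shape_jitter)
}

new_segment <- function(intervals, mu) {
  structure(list(intervals = intervals, mu = mu), class = "mlc_segment")
}

#' Sample a random deliverable MLC segment
#'
#' Draws a connected aperture roughly conformal to a randomly perturbed
#' ellipse about `target_center` (beam's-eye-view coordinates: linac X along
#' leaf rows, linac Y along leaf travel), with a log-uniform MU weight.
#' Adjacent open rows never change either edge by more than twice the leaf
#' width, so the aperture is smooth and connected.
#'
#' @param seed Integer seed; the sampler is a pure function of it.
#' @param machine A [machine_model()].
#' @param target_center Length-2 vector (linac X, linac Y) in mm.
#' @param target_radius Approximate aperture radius (mm); 0 degenerates to a
#'   single-row minimal opening.
#' @param config A [segment_config()].
#' @return An `mlc_segment`: an `n_leaf_rows x 2` matrix of open intervals
#'   (NA rows closed) and an MU weight.
#' @export
sample_segment <- function(seed, machine, target_center, target_radius,
                           config = segment_config()) {
  fx2 <- machine$field_x_extent / 2
  fy2 <- machine$field_y_extent / 2
  if (abs(target_center[1]) + target_radius > fx2 ||
      abs(target_center[2]) + target_radius > fy2) {
    stop(sprintf(
      "target (center %.1f, %.1f mm; radius %.1f mm) extends outside the %gx%g mm field",
      target_center[1], target_center[2], target_radius,
      machine$field_x_extent, machine$field_y_extent))
  }
  lw <- machine$leaf_width
  nr <- machine$n_leaf_rows
  with_seed(seed, {
    mu <- exp(runif(1, log(config$mu_range[1]), log(config$mu_range[2])))
    intervals <- matrix(NA_real_, nr, 2)
    if (target_radius <= 0) {
      r <- leaf_row_of(target_center[1], machine)
      intervals[r, ] <- target_center[2] + c(-0.5, 0.5) * config$min_opening
      return(new_segment(intervals, mu))
    }
    cx <- target_center[1] + runif(1, -0.15, 0.15) * target_radius
    cy <- target_center[2] + runif(1, -0.15, 0.15) * target_radius
    rx <- target_radius * runif(1, 0.8, 1.15)
    ry <- target_radius * runif(1, 0.8, 1.15)
    row_x <- leaf_row_bounds(seq_len(nr), machine)
    xc <- (row_x[, 1] + row_x[, 2]) / 2
    open <- which(abs(xc - cx) < rx)
    if (length(open) == 0) open <- leaf_row_of(cx, machine)
    chord <- ry * sqrt(pmax(0, 1 - ((xc[open] - cx) / rx)^2))
    # smooth noise on the per-row center and half-width (moving average)
    noise <- function() {
      u <- runif(length(open), -1, 1)
      if (length(u) >= 3) u <- stats::filter(u, rep(1 / 3, 3), sides = 2,
                                             circular = TRUE)
      config$shape_jitter * as.numeric(u)
    }
    h <- pmax(chord * (1 + noise()), config$min_opening / 2)
    ce <- cy + chord * noise()
    # enforce smooth edges outward from the widest row: the total edge motion
    # |dc| + |dh| between adjacent rows is scaled down to <= 2 leaf widths,
    # which bounds each individual edge change by 2 leaf widths
    anchor <- which.max(h)
    smooth_dir <- function(idx) {
      for (q in idx) {
        dc <- ce[q] - ce[q - sign(q - anchor)]
        dh <- h[q] - h[q - sign(q - anchor)]
        s <- abs(dc) + abs(dh)
        if (s > 2 * lw) {
          f <- 2 * lw / s
          ce[q] <<- ce[q - sign(q - anchor)] + dc * f
          h[q] <<- h[q - sign(q - anchor)] + dh * f
        }
      }
    }
    if (anchor < length(open)) smooth_dir((anchor + 1):length(open))
    if (anchor > 1) smooth_dir((anchor - 1):1)
    lo <- pmax(ce - h, -fy2)
    up <- pmin(ce + h, fy2)
    # clamping to the field preserves smoothness (edges move towards their
    # neighbours); fully-outside rows can only occur at the run's extremes,
    # but keep strictly the contiguous open run through the anchor anyway
    keep <- up > lo
    run <- keep
    if (any(!keep)) {
      run[] <- FALSE
      i <- anchor
      while (i >= 1 && keep[i]) { run[i] <- TRUE; i <- i - 1 }
      i <- anchor + 1
      while (i <= length(open) && keep[i]) { run[i] <- TRUE; i <- i + 1 }
    }
    intervals[open[run], 1] <- lo[run]
    intervals[open[run], 2] <- up[run]
    if (!any(!is.na(intervals[, 1]))) {
      r <- leaf_row_of(cx, machine)
      yc <- min(max(cy, -fy2 + config$min_opening / 2),
                fy2 - config$min_opening / 2)
      intervals[r, ] <- yc + c(-0.5, 0.5) * config$min_opening
    }
    new_segment(intervals, mu)
  })
}

#' Validate segment invariants
#'
#' Checks that a segment is an open, within-field, connected aperture whose
#' edges change by at most two leaf widths between adjacent open rows.
#' @param seg An `mlc_segment`.
#' @param machine A [machine_model()].
#' @return TRUE, or a character vector of violations.
#' @export
validate_segment <- function(seg, machine) {
  probs <- character()
  iv <- seg$intervals
  open <- which(!is.na(iv[, 1]))
  fy2 <- machine$field_y_extent / 2
  if (length(open) == 0) probs <- c(probs, "no open leaf row")
  if (!is.null(seg$mu) && seg$mu <= 0) probs <- c(probs, "mu_weight <= 0")
  if (length(open)) {
    if (any(iv[open, 1] > iv[open, 2])) probs <- c(probs, "lower > upper")
    if (any(iv[open, ] < -fy2 - 1e-9) || any(iv[open, ] > fy2 + 1e-9))
      probs <- c(probs, "interval outside field")
    if (length(open) > 1) {
      if (any(diff(open) != 1)) probs <- c(probs, "open rows not contiguous")
      d <- abs(apply(iv[open, , drop = FALSE], 2, diff))
      if (any(d > 2 * machine$leaf_width + 1e-9))
        probs <- c(probs, "edge change exceeds 2 leaf widths")
    }
  }
  if (length(probs)) probs else TRUE
}

#' Sample a synthetic phantom with ROI masks
#'
#' Generates an ellipsoidal body, an ellipsoidal planning target volume (PTV)
#' near the center, and four organ-at-risk masks chosen to exercise
#' dose-volume comparisons: a duodenum-like shell abutting the PTV, two
#' lateral kidney-like ellipsoids, and a cord-like posterior cylinder. OAR
#' masks never overlap the PTV; the PTV lies inside the body.
#'
#' @param seed Integer seed (bitwise-reproducible masks).
#' @param grid A [grid_spec()].
#' @return A `phantom`: grid plus logical masks `body`, `ptv`, `oars` (named).
#' @export
sample_phantom <- function(seed, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ext <- grid$dim * grid$spacing
  xs <- grid_coords(grid, 1); ys <- grid_coords(grid, 2); zs <- grid_coords(grid, 3)
  X <- array(rep(xs, times = grid$dim[2] * grid$dim[3]), grid$dim)
  Y <- array(rep(rep(ys, each = grid$dim[1]), times = grid$dim[3]), grid$dim)
  Z <- array(rep(zs, each = grid$dim[1] * grid$dim[2]), grid$dim)
  ellipsoid <- function(c0, r) {
    ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 + ((Z - c0[3]) / r[3])^2 <= 1
  }
  with_seed(seed, {
    body <- ellipsoid(c(0, 0, 0),
                      c(0.44, 0.40, 0.47) * ext * runif(3, 0.95, 1.05))
    rp <- pmin(runif(3, 14, 22), 0.22 * ext)
    cp <- c(runif(1, -6, 6), runif(1, 2, 10), runif(1, -6, 6))
    ptv <- ellipsoid(cp, rp) & body
    ax_d <- sqrt(((X - cp[1]) / rp[1])^2 + ((Y - cp[2]) / rp[2])^2 +
                   ((Z - cp[3]) / rp[3])^2)
    duo <- ax_d > 1 & ax_d <= 1 + runif(1, 0.4, 0.7) & (X >= cp[1] - rp[1] / 2)
    kid_r <- c(0.10, 0.08, 0.13) * ext
    k_l <- ellipsoid(c(0.26 * ext[1], -0.14 * ext[2], 0) * runif(3, 0.95, 1.05),
                     kid_r)
    k_r <- ellipsoid(c(-0.26 * ext[1], -0.14 * ext[2], 0) * runif(3, 0.95, 1.05),
                     kid_r)
    cord <- (X^2 + (Y + 0.30 * ext[2])^2) <= runif(1, 5, 7)^2
    oars <- list(duodenum = duo, kidney_left = k_l, kidney_right = k_r,
                 cord = cord)
    oars <- lapply(oars, function(m) m & body & !ptv)
    structure(list(grid = grid, body = body, ptv = ptv, oars = oars),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels; PTV %d vox; OARs: %s\n",
              paste(x$grid$dim, collapse = "x"), sum(x$ptv),
              paste(names(x$oars), collapse = ", ")))
  invisible(x)
}

# beam's-eye-view footprint of the PTV at a gantry angle:
# center (linac X, linac Y) and radius, mm relative to the isocenter
ptv_bev_footprint <- function(phantom, iso, gantry) {
  idx <- which(phantom$ptv, arr.ind = TRUE)
  g <- phantom$grid
  p <- sweep(sweep(idx - 1, 2, g$spacing, "*"), 2, g$origin + 0, "+")
  p <- sweep(p, 2, iso, "-")
  th <- gantry * pi / 180
  xb <- p[, 1] * cos(th) - p[, 2] * sin(th)
  zb <- p[, 3]
  cx <- (max(xb) + min(xb)) / 2
  cz <- (max(zb) + min(zb)) / 2
  r <- max((max(xb) - min(xb)) / 2, (max(zb) - min(zb)) / 2)
  list(center = c(cx, cz), radius = r)
}

#' Sample a synthetic step-and-shoot IMRT plan
#'
#' Eleven beams at the fixed gantry angle set, each with a random number of
#' segments conformal to the PTV's beam's-eye-view projection.
#'
#' @param seed Integer seed (per-fraction variability).
#' @param machine A [machine_model()].
#' @param phantom A [sample_phantom()] result (must contain a nonempty PTV).
#' @param n_segments_range Inclusive range of per-beam segment counts.
#' @param patient_id,fraction Identifiers stored in the plan.
#' @param prescription Prescription dose (cGy).
#' @param config A [segment_config()].
#' @param structure_seed Optional seed fixing the plan *structure* (per-beam
#'   segment counts and base aperture shapes). Fractionated plans of one
#'   patient share a `structure_seed`, emulating daily adaptive replanning:
#'   each fraction keeps the reference plan's structure while aperture
#'   positions and MU weights are re-optimized (jittered) for the day.
#' @return A `plan` object.
#' @export
sample_plan <- function(seed, machine, phantom,
                        n_segments_range = c(1, 6),
                        patient_id = "p01", fraction = 1L,
                        prescription = 3500, config = segment_config(),
                        structure_seed = NULL) {
  if (!any(phantom$ptv)) stop("phantom has an empty PTV mask")
  base <- if (is.null(structure_seed)) seed else structure_seed
  g <- phantom$grid
  idx <- which(phantom$ptv, arr.ind = TRUE)
  iso <- unname(colMeans(sweep(sweep(idx - 1, 2, g$spacing, "*"), 2,
                               g$origin, "+")))
  beams <- lapply(seq_along(FIXED_GANTRY_ANGLES), function(b) {
    ang <- FIXED_GANTRY_ANGLES[b]
    fp <- ptv_bev_footprint(phantom, iso, ang)
    ns <- with_seed(derive_seed(base, "nseg", b),
                    sample(seq(n_segments_range[1], n_segments_range[2]), 1))
    segs <- lapply(seq_len(ns), function(s) {
      jit <- with_seed(derive_seed(seed, "jit", b, s), runif(2, -0.2, 0.2))
      seg <- sample_segment(derive_seed(base, "seg", b, s), machine,
                            fp$center + jit * fp$radius,
                            fp$radius, config)
      seg$mu <- seg$mu *
        with_seed(derive_seed(seed, "mu", b, s), runif(1, 0.8, 1.25))
      seg
    })
    # delivery order: heaviest segment first (the order the TPS would emit)
    segs <- segs[order(-vapply(segs, function(s) s$mu, 1))]
    structure(list(gantry = ang, segments = segs, isocenter = iso),
              class = "beam")
  })
  structure(list(patient_id = patient_id, fraction = as.integer(fraction),
                 prescription = prescription, isocenter = iso, beams = beams),
            class = "plan")
}

#' @export
print.plan <- function(x, ...) {
  cat(sprintf("<plan> %s fx%d: %d beams, %d segments, prescription %g cGy\n",
              x$patient_id, x$fraction, length(x$beams),
              sum(vapply(x$beams, function(b) length(b$segments), 1L)),
              x$prescription))
  invisible(x)
}

#' Sample a cohort of patients, phantoms and fractionated plans
#'
#' The default emulates the study structure this package targets: 10 patients
#' with 5 fractionated step-and-shoot plans each, 11 fixed-angle beams per
#' plan, so 50 plans and 550 per-beam samples.
#'
#' @param seed Master seed.
#' @param n_patients,n_fractions Cohort shape.
#' @param grid Planning grid ([grid_spec()]).
#' @param machine A [machine_model()].
#' @param n_segments_range Per-beam segment count range.
#' @param config A [segment_config()].
#' @return A `cohort`: list of patients, each with a phantom and plans.
#' @export
sample_cohort <- function(seed, n_patients = 10, n_fractions = 5,
                          grid = grid_spec(96, 3), machine = machine_model(),
                          n_segments_range = c(1, 6),
                          config = segment_config()) {
  patients <- lapply(seq_len(n_patients), function(p) {
    pid <- sprintf("p%02d", p)
    ph <- sample_phantom(derive_seed(seed, "phantom", p), grid)
    plans <- lapply(seq_len(n_fractions), function(f) {
      sample_plan(derive_seed(seed, "plan", p, f), machine, ph,
                  n_segments_range, patient_id = pid, fraction = f,
                  config = config,
                  structure_seed = derive_seed(seed, "structure", p))
    })
    list(patient_id = pid, phantom = ph, plans = plans)
  })
  structure(list(patients = patients, machine = machine, grid = grid,
                 seed = seed), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  np <- length(x$patients)
  nf <- length(x$patients[[1]]$plans)
  cat(sprintf("<cohort> %d patients x %d fractions = %d plans (%d beams)\n",
              np, nf, np * nf, np * nf * length(FIXED_GANTRY_ANGLES)))
  invisible(x)
}

# binary aperture raster of one segment on pixel-center grids
# x_centers (linac X, mm), y_centers (linac Y, mm)
rasterize_segment <- function(seg, machine, x_centers, y_centers) {
  rows <- leaf_row_of(x_centers, machine)
  lo <- seg$intervals[rows, 1]
  up <- seg$intervals[rows, 2]
  lo[is.na(lo)] <- Inf
  up[is.na(up)] <- -Inf
  m <- outer(lo, y_centers, "<") & outer(up, y_centers, ">")
  storage.mode(m) <- "double"
  m
}

# separable Gaussian blur on a matrix, pitches in mm; kernel normalized so the
# image integral is preserved
gauss_blur <- function(m, sigma, pitch) {
  if (sigma <= 0) return(m)
  band <- function(n, pt) {
    r <- ceiling(3 * sigma / pt)
    k <- exp(-((-r:r) * pt)^2 / (2 * sigma^2))
    k <- k / sum(k)
    B <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- k[d + r + 1]
    }
    B
  }
  band(nrow(m), pitch[1]) %*% m %*% t(band(ncol(m), pitch[2]))
}

#' MU-weighted 2D fluence of a beam
#'
#' Rasterizes every segment aperture on the full machine field, sums them
#' with their MU weights, and applies an isotropic Gaussian penumbra.
#'
#' @param beam A beam from a [sample_plan()].
#' @param machine A [machine_model()].
#' @param resolution Raster pitch (mm).
#' @param sigma Penumbra Gaussian sigma (mm); 0 disables blurring.
#' @return List with `pixels` (rows along linac X, cols along linac Y),
#'   pixel-center coordinates and the resolution.
#' @export
fluence_2d <- function(beam, machine, resolution = 2, sigma = 3) {
  xs <- seq(-machine$field_x_extent / 2 + resolution / 2,
            machine$field_x_extent / 2 - resolution / 2 + 1e-9, by = resolution)
  ys <- seq(-machine$field_y_extent / 2 + resolution / 2,
            machine$field_y_extent / 2 - resolution / 2 + 1e-9, by = resolution)
  f <- matrix(0, length(xs), length(ys))
  for (seg in beam$segments) {
    f <- f + seg$mu * rasterize_segment(seg, machine, xs, ys)
  }
  f <- gauss_blur(f, sigma, c(resolution, resolution))
  list(pixels = f, x_centers = xs, y_centers = ys, resolution = resolution)
}

# --- idealized dose engine -------------------------------------------------

# beam-frame ingredients shared by forward_dose_3d and beam_bev_map:
# body mask rotated into the beam frame (grid centered on the isocenter),
# radiological depth along the beam, and the in-frame fluence raster
beam_frame_parts <- function(beam, phantom, machine, sigma) {
  g <- phantom$grid
  iso <- beam$isocenter
  lo <- g$origin
  hi <- g$origin + (g$dim - 1) * g$spacing
  if (any(iso < lo) || any(iso > hi)) stop("isocenter outside the dose grid")
  bf_grid <- grid_spec(g$dim, g$spacing, origin = iso - (g$dim - 1) * g$spacing / 2)
  body <- phantom$body
  storage.mode(body) <- "double"
  body_b <- resample_affine(dose3d(body, g), bf_grid, R = rot_z(-beam$gantry),
                            center = iso)$values
  # the source sits at +y_b: depth accumulates towards decreasing y index
  dy <- g$spacing[2]
  depth <- body_b
  ny <- g$dim[2]
  acc <- matrix(0, g$dim[1], g$dim[3])
  for (j in ny:1) {
    sl <- body_b[, j, ]
    acc <- acc + sl * dy
    depth[, j, ] <- acc - sl * dy / 2
  }
  xb <- (seq_len(g$dim[1]) - 1 - (g$dim[1] - 1) / 2) * g$spacing[1]
  zb <- (seq_len(g$dim[3]) - 1 - (g$dim[3] - 1) / 2) * g$spacing[3]
  f <- matrix(0, length(xb), length(zb))
  for (seg in beam$segments) {
    f <- f + seg$mu * rasterize_segment(seg, machine, xb, zb)
  }
  f <- gauss_blur(f, sigma, c(g$spacing[1], g$spacing[3]))
  list(bf_grid = bf_grid, body_b = body_b, depth = depth, fluence = f,
       xb = xb, zb = zb, iso = iso)
}

# per-beam dose cube in the beam frame
beam_frame_dose <- function(parts, mu_attenuation) {
  g <- parts$bf_grid
  att <- exp(-mu_attenuation * parts$depth) * parts$body_b
  f3 <- array(0, g$dim)
  fl <- parts$fluence
  for (j in seq_len(g$dim[2])) f3[, j, ] <- fl
  f3 * att
}

#' Idealized forward dose engine
#'
#' Computes the 3D dose of a plan by attenuated back-projection: each beam's
#' MU-weighted fluence is projected through the body along the beam axis with
#' exponential attenuation, rotated to the gantry angle about the isocenter,
#' and beams are summed. Deterministic and exactly linear in MU weights. This
#' engine stands in for a clinical dose calculation and is used consistently
#' for both ground-truth and predicted plans so comparisons are internally
#' valid.
#'
#' @param plan A `plan`.
#' @param phantom The phantom the plan was made for.
#' @param machine A [machine_model()].
#' @param mu_attenuation Linear attenuation coefficient inside the body
#'   (1/mm); 0 disables attenuation.
#' @param sigma Penumbra sigma (mm).
#' @param per_beam Keep the individual beam doses.
#' @return List with `total` ([dose3d()]) and, if requested, `beams` (a named
#'   list of per-beam `dose3d`).
#' @export
forward_dose_3d <- function(plan, phantom, machine,
                            mu_attenuation = 0.005, sigma = 3,
                            per_beam = TRUE) {
  g <- phantom$grid
  total <- array(0, g$dim)
  beams <- list()
  for (b in seq_along(plan$beams)) {
    beam <- plan$beams[[b]]
    parts <- beam_frame_parts(beam, phantom, machine, sigma)
    d_bf <- beam_frame_dose(parts, mu_attenuation)
    d_pat <- resample_affine(dose3d(d_bf, parts$bf_grid), g,
                             R = rot_z(beam$gantry), center = parts$iso)
    nm <- sprintf("beam%02d", b)
    d_pat$beam_ref <- nm
    if (per_beam) beams[[nm]] <- d_pat
    total <- total + d_pat$values
  }
  out <- list(total = dose3d(total, g, beam_ref = "plan_sum"))
  if (per_beam) out$beams <- beams
  out
}

#' Beam's-eye-view dose map of a single beam, computed in the beam frame
#'
#' Shortcut equivalent of running the idealized engine and then the
#' shift / rotate / project preprocessing chain: the per-beam dose is formed
#' directly in the beam-aligned frame and summed along the beam axis, skipping
#' the two inverse/forward rotations. Returns the unnormalized map embedded in
#' the machine field raster.
#'
#' @inheritParams forward_dose_3d
#' @param beam A single beam.
#' @param size Output raster size (pixels per side).
#' @param raster `"grid"`: raster over the planning grid's BEV extents
#'   (centered on the isocenter) — the raster training pairs use; `"field"`:
#'   embed in the full machine field raster.
#' @return A `size x size` matrix (rows along linac X) with attributes
#'   `extent_x`, `extent_y` (mm relative to the isocenter).
#' @export
beam_bev_map <- function(beam, phantom, machine, mu_attenuation = 0.005,
                         sigma = 3, size = 128,
                         raster = c("grid", "field")) {
  raster <- match.arg(raster)
  parts <- beam_frame_parts(beam, phantom, machine, sigma)
  d_bf <- beam_frame_dose(parts, mu_attenuation)
  bev <- colSums(aperm(d_bf, c(2, 1, 3)))  # sum along the beam axis
  sp <- phantom$grid$spacing
  src_x <- range(parts$xb) + c(-0.5, 0.5) * sp[1]
  src_y <- range(parts$zb) + c(-0.5, 0.5) * sp[3]
  if (raster == "grid") {
    out <- resample2d_extent(bev, src_x, src_y, size, size, src_x, src_y,
                             edge = "clamp")
    ex <- src_x; ey <- src_y
  } else {
    out <- map_to_field_raster(bev, src_x, src_y, machine, size)
    ex <- c(-1, 1) * machine$field_x_extent / 2
    ey <- c(-1, 1) * machine$field_y_extent / 2
  }
  attr(out, "extent_x") <- ex
  attr(out, "extent_y") <- ey
  out
}

# embed a BEV map with known mm extents (relative to the isocenter) into the
# full machine field raster
map_to_field_raster <- function(map, x_extent, y_extent, machine, size) {
  resample2d_extent(map, x_extent, y_extent, size, size,
                    c(-1, 1) * machine$field_x_extent / 2,
                    c(-1, 1) * machine$field_y_extent / 2)
}
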