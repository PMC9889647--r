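dose_set <- forward_dose_3d(fix_plan_small, fix_phantom_small, fix_machine)

test_that("per-beam doses sum to the plan dose and unknown beams error", {
  tot <- Reduce(`+`, lapply(dose_set$beams, function(b) b$values))
  expect_equal(tot, dose_set$total$values, tolerance = 1e-12)
  expect_s3_class(extract_beam_dose(dose_set$beams, "beam03"), "dose3d")
  expect_error(extract_beam_dose(dose_set$beams, "beam99"), "available")
})

test_that("resampling to an identical grid is the identity", {
  d <- dose_set$beams[["beam01"]]
  r <- resample_to_planning_grid(d, d$grid)
  expect_equal(r$values, d$values, tolerance = 1e-12)
  # constant fields stay constant under any compatible resampling
  dc <- dose3d(array(7, fix_grid_small$dim), fix_grid_small)
  g2 <- grid_spec(16, 6)
  rc <- resample_to_planning_grid(dc, g2)
  expect_true(all(abs(rc$values - 7) < 1e-12))
  far <- grid_spec(8, 2, origin = c(1e4, 1e4, 1e4))
  expect_error(resample_to_planning_grid(dc, far), "disjoint")
})

test_that("smooth fields keep their integral under 2x upsampling", {
  # a compact Gaussian blob (negligible mass at the grid boundary)
  xs <- seq_len(16) - 8.5
  r2 <- outer(outer(xs^2, xs^2, "+"), xs^2, "+")
  v <- array(exp(-r2 / 8), c(16, 16, 16))
  d <- dose3d(v, grid_spec(16, 6))
  up <- resample_to_planning_grid(d, grid_spec(32, 3))
  int_src <- sum(v) * 6^3
  int_up <- sum(up$values) * 3^3
  expect_lt(abs(int_up - int_src) / int_src, 0.03)
})

test_that("isocenter shifts behave as exact rolls and invert cleanly", {
  d <- dose_set$beams[["beam01"]]
  ctr <- d$grid$origin + (d$grid$dim - 1) * d$grid$spacing / 2
  # isocenter already at center: identity
  s0 <- shift_to_isocenter(d, ctr)
  expect_equal(s0$values, d$values, tolerance = 1e-12)
  # integer-voxel shift: exact roll with zero fill
  iso <- ctr + c(d$grid$spacing[1], 0, 0)
  s1 <- shift_to_isocenter(d, iso)
  expect_equal(s1$values[1:(d$grid$dim[1] - 1), , ],
               d$values[2:d$grid$dim[1], , ], tolerance = 1e-12)
  expect_true(all(s1$values[d$grid$dim[1], , ] == 0))
  # shift then inverse shift: identity away from the rolled-in edge
  s2 <- shift_to_isocenter(s1, ctr - c(d$grid$spacing[1], 0, 0))
  expect_lt(max(abs(s2$values[2:23, , ] - d$values[2:23, , ])) /
              max(d$values), 1e-6)
  expect_error(shift_to_isocenter(d, ctr + 1e4), "outside")
})

test_that("BEV rotation is exact at right angles and spares symmetry", {
  d <- dose_set$beams[["beam02"]]
  r0 <- rotate_to_bev(d, 0)
  expect_equal(r0$values, d$values, tolerance = 1e-12)
  r <- d
  for (i in 1:4) r <- rotate_to_bev(r, 90)
  expect_lt(max(abs(r$values - d$values)) / max(d$values), 1e-6)
  # cylindrically symmetric dose is invariant under any angle
  n <- fix_grid_small$dim[1]
  xs <- seq_len(n) - (n + 1) / 2
  rad2 <- outer(xs^2, xs^2, "+")
  cyl <- array(exp(-rad2 / 32), c(n, n, n))
  dc <- dose3d(cyl, fix_grid_small)
  rc <- rotate_to_bev(dc, 37)
  # compare inside the inscribed cylinder (outside is rotated-in zero fill)
  core <- array(rad2 <= (n / 4)^2, c(n, n, n))
  expect_lt(max(abs(rc$values[core] - cyl[core])) / max(cyl), 0.02)
})

test_that("BEV projection sums along the beam axis and commutes with shift", {
  slab <- array(0, c(8, 8, 8))
  slab[3:6, 2:5, 4] <- 1   # 4-voxel-thick along y inside footprint
  d <- dose3d(slab, grid_spec(8, 4))
  mp <- project_bev(d)
  expect_equal(mp[4, 4], 4)
  expect_equal(mp[1, 1], 0)
  expect_equal(project_bev(dose3d(array(0, c(8, 8, 8)), grid_spec(8, 4))),
               matrix(0, 8, 8))
  # transverse translation commutes with projection (exact for integer roll)
  d2 <- shift_to_isocenter(d, d$grid$origin + (d$grid$dim - 1) *
                             d$grid$spacing / 2 + c(4, 0, 0))
  mp2 <- project_bev(d2)
  expect_equal(mp2[1:7, ], mp[2:8, ], tolerance = 1e-12)
})

test_that("normalization rescales to [0, 1] and is invertible on smooth maps", {
  cm <- matrix(5.5, 40, 40)
  nm <- normalize_resample(cm, 128)
  expect_true(all(abs(nm$pixels - 1) < 1e-12))
  expect_equal(nm$scale, 5.5)
  # max is exactly 1 for any nonzero input
  m <- matrix(runif(64^2), 64)
  expect_equal(max(normalize_resample(m, 128)$pixels), 1)
  # all-zero input: flagged via scale = 0
  z <- normalize_resample(matrix(0, 16, 16), 32)
  expect_equal(z$scale, 0)
  expect_true(all(z$pixels == 0))
  expect_error(normalize_resample(matrix(-1, 4, 4)), "negative")
  # de-normalization round trip on a smooth map
  xs <- seq(-3, 3, length.out = 80)
  sm <- exp(-outer(xs^2, xs^2, "+") / 4)
  nn <- normalize_resample(sm, 128)
  back <- leafseq:::resample2d_extent(nn$pixels * nn$scale, c(0, 1), c(0, 1),
                                      80, 80, c(0, 1), c(0, 1))
  core <- sm > 0.05
  expect_lt(max(abs(back[core] - sm[core])) / max(sm), 0.02)
})

test_that("aperture stacks are MU-weighted, ordered, zero-padded binaries", {
  beam <- fix_plan_small$beams[[3]]
  st <- segments_from_controlpoints(beam, fix_machine, 128)
  expect_equal(dim(st$channels), c(128, 128, 6))
  ns <- st$n_real_segments
  expect_equal(ns, length(beam$segments))
  if (ns < 6) expect_true(all(st$channels[, , (ns + 1):6] == 0))
  for (i in seq_len(ns)) {
    ch <- st$channels[, , i]
    vals <- unique(as.numeric(ch))
    expect_setequal(round(vals[vals > 0], 12),
                    round(beam$segments[[i]]$mu / st$mu_scale, 12))
  }
  # fully open single segment: all ones inside the field footprint
  iv <- matrix(rep(c(-109.9, 109.9), each = 80), 80)
  wide <- structure(list(intervals = iv, mu = 10), class = "mlc_segment")
  bw <- structure(list(gantry = 0, segments = list(wide),
                       isocenter = c(0, 0, 0)), class = "beam")
  stw <- segments_from_controlpoints(bw, fix_machine, 64, mu_scale = 10)
  expect_true(all(stw$channels[, , 1] == 1))
  expect_true(all(stw$channels[, , 2:6] == 0))
  # fully closed segment rejected
  closed <- structure(list(intervals = matrix(NA_real_, 80, 2), mu = 1),
                      class = "mlc_segment")
  bc <- bw; bc$segments <- list(closed)
  expect_error(segments_from_controlpoints(bc, fix_machine, 64), "closed")
})

test_that("rasterized open areas match the analytic interval areas", {
  seg <- sample_segment(31, fix_machine, c(0, 0), 30)
  fr <- leafseq:::field_raster_centers(fix_machine, 256)
  st <- leafseq:::rasterize_segment(seg, fix_machine, fr$x, fr$y)
  px_area <- (572 / 256) * (220 / 256)
  open <- !is.na(seg$intervals[, 1])
  analytic <- sum((seg$intervals[open, 2] - seg$intervals[open, 1]) *
                    fix_machine$leaf_width)
  expect_lt(abs(sum(st) * px_area - analytic) / analytic, 0.05)
})

test_that("more than six segments errors by default and merges on request", {
  beam <- fix_plan_small$beams[[1]]
  seg <- beam$segments[[1]]
  b8 <- beam
  b8$segments <- rep(list(seg), 8)
  expect_error(segments_from_controlpoints(b8, fix_machine, 32), "6 channels")
  st <- segments_from_controlpoints(b8, fix_machine, 32, overflow = "merge")
  expect_equal(st$n_real_segments, 6)
})

test_that("BEV dose maps correlate with weighted aperture sums", {
  # the well-posedness property at reduced scale (full scale in acceptance)
  beam <- fix_plan_small$beams[[5]]
  bev <- beam_bev_map(beam, fix_phantom_small, fix_machine, size = 64)
  st <- segments_from_controlpoints(beam, fix_machine, 64,
                                    extent_x = attr(bev, "extent_x"),
                                    extent_y = attr(bev, "extent_y"))
  chsum <- apply(st$channels, c(1, 2), sum)
  expect_gt(cor(as.numeric(bev), as.numeric(chsum)), 0.9)
})

test_that("training pairs carry registered inputs/targets and metadata", {
  co <- sample_cohort(3, n_patients = 1, n_fractions = 1,
                      grid = fix_grid_small)
  pr <- build_training_pairs(co, size = 32)
  expect_length(pr$pairs, 11)
  expect_equal(dim(pr$pairs[[1]]$x), c(32, 32))
  expect_equal(dim(pr$pairs[[1]]$y), c(32, 32, 6))
  expect_true(all(pr$meta$scale > 0))
  expect_equal(nrow(pr$meta), 11)
  # deterministic: byte-identical on rebuild
  pr2 <- build_training_pairs(co, size = 32)
  expect_identical(pr$pairs, pr2$pairs)
})
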