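test_that("machine geometry derives exactly 80 leaf rows", {
  m <- machine_model()
  expect_equal(m$n_leaf_rows * m$leaf_width, m$field_x_extent)
  expect_equal(m$n_leaf_rows, 80L)
  expect_false(m$leaf_travel_axis == m$diaphragm_axis)
  expect_error(machine_model(leaf_width = 7), "integer multiple")
})

test_that("segment sampler is a pure function of its seed", {
  s1 <- sample_segment(5, fix_machine, c(0, 10), 25)
  s2 <- sample_segment(5, fix_machine, c(0, 10), 25)
  expect_identical(s1, s2)
  s3 <- sample_segment(6, fix_machine, c(0, 10), 25)
  expect_false(identical(s1$intervals, s3$intervals))
})

test_that("degenerate zero-radius target opens a single minimal row", {
  s <- sample_segment(3, fix_machine, c(12, -5), 0)
  open <- which(!is.na(s$intervals[, 1]))
  expect_length(open, 1)
  expect_equal(open, leafseq:::leaf_row_of(12, fix_machine))
  expect_equal(diff(s$intervals[open, ]), segment_config()$min_opening,
               ignore_attr = TRUE)
})

test_that("targets outside the field are rejected", {
  expect_error(sample_segment(1, fix_machine, c(0, 100), 30), "outside")
  expect_error(sample_segment(1, fix_machine, c(280, 0), 20), "outside")
})

test_that("sampled segments satisfy connectivity and field invariants", {
  set.seed(99)
  for (i in 1:1000) {
    s <- sample_segment(i, fix_machine,
                        c(runif(1, -80, 80), runif(1, -60, 60)),
                        runif(1, 0, 40))
    expect_true(isTRUE(validate_segment(s, fix_machine)))
    expect_gt(s$mu, 0)
  }
})

test_that("phantom masks are reproducible and geometrically consistent", {
  p1 <- sample_phantom(11, fix_grid_small)
  expect_identical(p1$body, fix_phantom_small$body)
  expect_identical(p1$ptv, fix_phantom_small$ptv)
  # PTV inside body
  expect_true(all((p1$ptv & p1$body) == p1$ptv))
  expect_gt(sum(p1$ptv), 0)
  # OARs never overlap the PTV; at least 4 of them
  expect_gte(length(p1$oars), 4)
  for (o in p1$oars) expect_equal(sum(o & p1$ptv), 0)
})

test_that("plans have the fixed 11-angle beam set and bounded segments", {
  expect_length(fix_plan_small$beams, 11)
  expect_equal(vapply(fix_plan_small$beams, function(b) b$gantry, 1),
               FIXED_GANTRY_ANGLES)
  p1 <- sample_plan(4, fix_machine, fix_phantom_small,
                    n_segments_range = c(1, 1))
  expect_true(all(vapply(p1$beams, function(b) length(b$segments), 1L) == 1))
  empty <- fix_phantom_small
  empty$ptv[] <- FALSE
  expect_error(sample_plan(1, fix_machine, empty, patient_id = "x"),
               "empty PTV")
})

test_that("cohort counts match the study structure", {
  co <- sample_cohort(2, n_patients = 3, n_fractions = 2,
                      grid = fix_grid_small)
  expect_length(co$patients, 3)
  n_plans <- sum(vapply(co$patients, function(p) length(p$plans), 1L))
  expect_equal(n_plans, 6)
  n_beams <- sum(vapply(co$patients, function(p)
    sum(vapply(p$plans, function(pl) length(pl$beams), 1L)), 1L))
  expect_equal(n_beams, 6 * 11)
})

test_that("fluence is the weighted aperture sum with integral preserved", {
  beam <- fix_plan_small$beams[[1]]
  seg <- beam$segments[[1]]
  b1 <- structure(list(gantry = 0, segments = list(seg),
                       isocenter = c(0, 0, 0)), class = "beam")
  f0 <- fluence_2d(b1, fix_machine, resolution = 2, sigma = 0)
  # sigma = 0: exactly mu inside the aperture, 0 outside
  expect_setequal(unique(as.numeric(f0$pixels)), c(0, seg$mu))
  # linearity: two copies with weights w1, w2
  s2 <- seg; s2$mu <- 2 * seg$mu
  b2 <- b1; b2$segments <- list(seg, s2)
  f2 <- fluence_2d(b2, fix_machine, resolution = 2, sigma = 0)
  expect_equal(f2$pixels, 3 * f0$pixels)
  # Gaussian penumbra preserves the integral (away from the field edge)
  fb <- fluence_2d(b1, fix_machine, resolution = 2, sigma = 3)
  open_area <- sum(f0$pixels > 0) * 4  # mm^2
  expect_equal(sum(fb$pixels) * 4, seg$mu * open_area, tolerance = 1e-6)
})

test_that("dose engine is exactly linear in MU and flat when mu = 0", {
  plan <- fix_plan_small
  d1 <- forward_dose_3d(plan, fix_phantom_small, fix_machine,
                        per_beam = FALSE)$total
  plan2 <- plan
  for (b in seq_along(plan2$beams)) {
    for (s in seq_along(plan2$beams[[b]]$segments)) {
      plan2$beams[[b]]$segments[[s]]$mu <-
        2 * plan2$beams[[b]]$segments[[s]]$mu
    }
  }
  d2 <- forward_dose_3d(plan2, fix_phantom_small, fix_machine,
                        per_beam = FALSE)$total
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)

  # mu = 0, single wide-open segment: dose constant along each ray in body
  iv <- matrix(rep(c(-60, 60), each = 80), 80)
  wide <- structure(list(intervals = iv, mu = 1), class = "mlc_segment")
  b0 <- structure(list(gantry = 0, segments = list(wide),
                       isocenter = c(0, 0, 0)), class = "beam")
  pl0 <- structure(list(patient_id = "t", fraction = 1L, prescription = 100,
                        isocenter = c(0, 0, 0), beams = list(b0)),
                   class = "plan")
  d0 <- forward_dose_3d(pl0, fix_phantom_small, fix_machine,
                        mu_attenuation = 0, sigma = 0,
                        per_beam = FALSE)$total
  # pick an interior column along the beam axis (y) well inside body & field
  ctr <- 12
  col <- d0$values[ctr, 6:18, ctr]
  body_col <- fix_phantom_small$body[ctr, 6:18, ctr]
  expect_true(all(abs(col[body_col] - 1) < 1e-9))
})

test_that("dose field co-rotates with the plan-and-phantom frame", {
  # rotating every gantry angle by 90 degrees equals rotating the dose
  # volume by 90 degrees about the SI axis, within interpolation error,
  # for a rotationally-placed phantom (use a centered spherical body/PTV)
  g <- grid_spec(24, 6)
  ph <- sample_phantom(21, g)
  # symmetrize: sphere body around center so rotation maps body onto itself
  xs <- seq_len(24) - 12.5
  R2 <- outer(outer(xs^2, xs^2, "+"), xs^2, "+")
  ph$body <- array(R2 <= 10^2, c(24, 24, 24))
  ph$ptv <- array(R2 <= 4^2, c(24, 24, 24))
  pl <- sample_plan(5, fix_machine, ph, n_segments_range = c(1, 2))
  d1 <- forward_dose_3d(pl, ph, fix_machine, per_beam = FALSE)$total
  pl90 <- pl
  for (b in seq_along(pl90$beams)) {
    pl90$beams[[b]]$gantry <- (pl90$beams[[b]]$gantry + 90) %% 360
  }
  d90 <- forward_dose_3d(pl90, ph, fix_machine, per_beam = FALSE)$total
  # d90(p) = d1(R(90) p): an exact axis permutation on a centered grid
  rot <- aperm(d1$values, c(2, 1, 3))[, 24:1, ]
  err <- max(abs(d90$values - rot)) / max(d1$values)
  expect_lt(err, 0.02)
})
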