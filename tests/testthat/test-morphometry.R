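test_that("extremal rim points agree with exhaustive search and symmetry", {
  cfg <- fast_config()
  hip <- axisym_hip(30)
  e <- lateral_rim_point(hip, cfg)
  r <- hip$sphere$radius
  expect_lt(max(abs(e - (hip$sphere$center +
                           r * c(sin(30 * DEG), 0, cos(30 * DEG))))), 1e-6)
  a <- anterolateral_rim_point(hip, cfg)
  expect_lt(max(abs(a - (hip$sphere$center +
                           r * c(sin(30 * DEG) * cos(65 * DEG),
                                 sin(30 * DEG) * sin(65 * DEG),
                                 cos(30 * DEG))))), 1e-3)
  # false-profile angle -> 0 degenerates to the lateral point
  cfg0 <- measurement_config(false_profile_deg = 1e-9,
                             area_grid_resolution = 0.4)
  expect_equal(anterolateral_rim_point(hip, cfg0), lateral_rim_point(hip, cfg0))

  # mirrored left hip returns the mirror-image point
  left <- mirror_hip(hip)
  el <- lateral_rim_point(left, cfg)
  expect_lt(max(abs(el - e * c(-1, 1, 1))), 1e-6)

  # brute-force argmax oracle on modulated, tilted rims
  withr::local_seed(5)
  for (i in 1:10) {
    hip2 <- generate_hip(synthetic_hip_params(
      rim_colatitude_deg = runif(1, 25, 45), rim_mod_amp_deg = runif(1, 0, 8),
      rim_mod_phase_deg = runif(1, -180, 180), rim_noise_deg = 0,
      n_rim_points = 3600
    ))
    posed <- apply_pose(hip2, make_tilt_pose(hip2$frame, runif(1, -30, 30)))
    w <- sweep(posed$rim$points, 2, posed$sphere$center)
    e_lat <- lateral_rim_point(posed, cfg)
    expect_equal(e_lat[1] - posed$sphere$center[1], max(w[, 1]),
                 tolerance = 1e-9)
    fp <- 65 * DEG
    u <- c(cos(fp), sin(fp), 0)
    e_al <- anterolateral_rim_point(posed, cfg)
    expect_equal(sum((e_al - posed$sphere$center) * u), max(w %*% u),
                 tolerance = 1e-9)
  }
})

test_that("LCEA follows the arctan(tan(theta)/cos(phi)) law under tilt", {
  cfg <- fast_config()
  withr::local_seed(6)
  for (i in 1:10) {
    th <- runif(1, 20, 50)
    hip <- axisym_hip(th, r = runif(1, 20, 28))
    for (phi in seq(-30, 30, 10)) {
      posed <- apply_pose(hip, make_tilt_pose(hip$frame, phi))
      got <- measure_lcea(posed, cfg)
      closed <- atan(tan(th * DEG) / cos(phi * DEG)) / DEG
      expect_lt(abs(got - closed), 0.1)
      expect_lt(abs(got - oracle_lcea(posed$rim$points, posed$sphere$center)),
                0.02)
    }
  }
})

test_that("ACEA equals LCEA at neutral for axisymmetric cups and increases with tilt", {
  cfg <- fast_config()
  for (th in c(25, 30, 40)) {
    hip <- axisym_hip(th)
    expect_lt(abs(measure_acea(hip, cfg) - measure_lcea(hip, cfg)), 0.1)
    acea <- vapply(seq(-30, 30, 5), function(phi) {
      posed <- apply_pose(hip, make_tilt_pose(hip$frame, phi))
      measure_acea(posed, cfg)
    }, numeric(1))
    expect_true(all(diff(acea) > 0))
    expect_lt(max(abs(acea - vapply(seq(-30, 30, 5), function(phi) {
      posed <- apply_pose(hip, make_tilt_pose(hip$frame, phi))
      oracle_acea(posed$rim$points, posed$sphere$center)
    }, numeric(1)))), 0.1)
  }
})

test_that("coverage matches the polar-cap closed form and the generative oracle", {
  hip45 <- axisym_hip(45)
  expect_lt(abs(compute_coverage(hip45, measurement_config()) - 0.5), 0.005)

  # full superior hemisphere: equatorial rim built directly
  psi <- seq(0, 2 * pi, length.out = 361)[-361]
  ctr <- hip45$sphere$center
  eq_rim <- rim_curve(sweep(24 * cbind(cos(psi), sin(psi), 0), 2, ctr, "+"))
  full <- hip_model(side = "right", sphere = head_sphere(ctr, 24),
                    rim = eq_rim, landmarks = hip45$landmarks)
  expect_equal(compute_coverage(full, fast_config()), 1.0, tolerance = 1e-6)

  # rim shrunk toward the pole: coverage tends to zero
  tiny <- axisym_hip(6)
  expect_lt(compute_coverage(tiny, fast_config()), 0.02)

  # generative Monte-Carlo oracle on a modulated cup across tilts
  params <- synthetic_hip_params(rim_colatitude_deg = 38, rim_mod_amp_deg = 9,
                                 rim_mod_phase_deg = -90, rim_noise_deg = 0)
  hip <- generate_hip(params)
  for (phi in c(-20, 0, 20)) {
    posed <- apply_pose(hip, make_tilt_pose(hip$frame, phi))
    got <- compute_coverage(posed, measurement_config())
    expect_lt(abs(got - oracle_coverage_mc(params, phi)), 0.01)
  }
})

test_that("all three measures are invariant to mirroring and rigid motion", {
  cfg <- fast_config()
  params <- synthetic_hip_params(rim_colatitude_deg = 36, rim_mod_amp_deg = 7,
                                 rim_mod_phase_deg = -70, rim_noise_deg = 0)
  hip <- generate_hip(params)
  mir <- mirror_hip(hip)
  expect_lt(abs(measure_lcea(hip, cfg) - measure_lcea(mir, cfg)), 1e-6)
  expect_lt(abs(measure_acea(hip, cfg) - measure_acea(mir, cfg)), 1e-6)
  expect_lt(abs(compute_coverage(hip, cfg) - compute_coverage(mir, cfg)), 1e-6)

  withr::local_seed(8)
  rm <- random_rigid_motion()
  moved <- transform_hip(hip, rm$R, rm$t)
  expect_lt(abs(measure_lcea(hip, cfg) - measure_lcea(moved, cfg)), 1e-6)
  expect_lt(abs(measure_acea(hip, cfg) - measure_acea(moved, cfg)), 1e-6)
  expect_lt(abs(compute_coverage(hip, cfg) - compute_coverage(moved, cfg)), 1e-6)
})

test_that("tilt sweeps are consistent with direct measurement and symmetric for axisymmetric cups", {
  cfg <- fast_config()
  hip <- axisym_hip(30)
  sweep_tbl <- tilt_sweep(hip, cfg)
  expect_equal(nrow(sweep_tbl), 13)
  expect_equal(sweep_tbl$app_tilt_deg, seq(-30, 30, 5))
  neutral <- sweep_tbl[sweep_tbl$app_tilt_deg == 0, ]
  expect_equal(neutral$lcea_deg, measure_lcea(hip, cfg), tolerance = 1e-9)
  expect_equal(neutral$acea_deg, measure_acea(hip, cfg), tolerance = 1e-9)
  expect_equal(neutral$coverage, compute_coverage(hip, cfg), tolerance = 1e-9)
  # LCEA even in tilt for an axisymmetric cup
  lc <- sweep_tbl$lcea_deg
  expect_lt(max(abs(lc - rev(lc))), 0.05)

  single <- tilt_sweep(hip, measurement_config(tilt_grid = 0,
                                               area_grid_resolution = 0.4))
  expect_equal(single$lcea_deg, neutral$lcea_deg, tolerance = 1e-9)
  expect_error(tilt_sweep(apply_pose(hip, make_tilt_pose(hip$frame, 5)), cfg),
               class = "hipmorph_validation")
})

test_that("cohort sweeps pivot to the long format expected by the statistics stage", {
  cfg <- fast_config(tilt_grid = c(-10, 0, 10))
  hips <- list(axisym_hip(30), mirror_hip(axisym_hip(35)))
  long <- as_cohort_table(measure_cohort(hips, cfg))
  expect_equal(nrow(long), 2 * 3 * 3)
  expect_setequal(unique(long$measure), c("acea", "lcea", "coverage"))
  expect_true(all(long$value[long$measure == "coverage"] >= 0 &
                    long$value[long$measure == "coverage"] <= 1))
})
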