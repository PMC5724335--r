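test_that("phase-to-displacement recovers known displacements", {
  # zero phase everywhere -> zero displacement
  dims <- c(32, 32, 3)
  zero <- array(0, dims)
  mag <- array(1, dims)
  fld <- phase_to_displacement(zero, zero, mag, mask = matrix(TRUE, 32, 32),
                               encoding_frequency = 0.10)
  expect_true(all(abs(fld$ux) < 1e-12) && all(abs(fld$uy) < 1e-12))

  # wrap-free 3 mm translation: exact recovery at every masked pixel
  ch <- cached_chain("trans3", dense_phantom_spec(
    grid_size = 80, n_frames = 11,
    deformation_law = list(type = "translation", dx = 3, dy = 0)))
  v <- ch$fld$valid[, , 6]
  expect_lt(max(abs(ch$fld$ux[, , 6][v] - 3)), 1e-6)
  expect_lt(max(abs(ch$fld$uy[, , 6][v])), 1e-6)

  # 12 mm translation wraps (phase 2.4*pi); temporal seeding from the ramped
  # activation recovers the absolute displacement
  ch12 <- run_dense_chain(dense_phantom_spec(
    grid_size = 96, n_frames = 21, annulus_inner_radius = 18,
    annulus_outer_radius = 26,
    deformation_law = list(type = "translation", dx = 12, dy = 0)))
  v12 <- ch12$fld$valid[, , 11]
  expect_lt(max(abs(ch12$fld$ux[, , 11][v12] - 12)), 1e-6)
})

test_that("trajectory building smooths and guards its polynomial order", {
  ch <- cached_chain("trans3", dense_phantom_spec(
    grid_size = 80, n_frames = 11,
    deformation_law = list(type = "translation", dx = 3, dy = 0)))
  # noiseless rigid translation: every trajectory is the same straight line
  ok <- ch$tr$valid[, 11]
  dx6 <- ch$tr$pos[ok, 1, 6] - ch$tr$X0[ok, 1]
  expect_lt(diff(range(dx6)), 1e-9)
  dy6 <- ch$tr$pos[ok, 2, 6] - ch$tr$X0[ok, 2]
  expect_lt(max(abs(dy6)), 1e-6)
  # interpolating order rejected
  expect_error(build_trajectories(ch$fld, ch$ph$mask_ref, poly_order = 10),
               "interpolate")
})

test_that("phase noise is suppressed below 0.3 mm RMS by the fitting chain", {
  ch <- run_dense_chain(dense_phantom_spec(
    grid_size = 96, n_frames = 15, noise_sd_phase = 0.1, seed = 5,
    deformation_law = list(type = "incompressible-annulus", delta = -120)))
  truth <- ch$ph$truth
  ok <- ch$tr$valid[, 15]
  # match tracked elements to truth rows via the shared reference index
  m <- match(ch$tr$ref_index, truth$ref_index)
  errs <- sqrt((ch$tr$pos[ok, 1, ] - ch$tr$X0[ok, 1] - truth$ux[m[ok], ])^2 +
                 (ch$tr$pos[ok, 2, ] - ch$tr$X0[ok, 2] - truth$uy[m[ok], ])^2)
  expect_lt(sqrt(mean(errs^2)), 0.3)
})

test_that("Green-Lagrange strain is objective and matches closed forms", {
  # identity motion: exactly zero
  tr_id <- analytic_trajectories(function(X, s) X)
  sc_id <- compute_strains(tr_id, c(0, 0))
  expect_lt(max(abs(sc_id$ecc), na.rm = TRUE), 1e-10)

  # rigid rotation by 20 degrees: exactly zero (objectivity)
  rot <- function(X, s) {
    phi <- 20 * pi / 180 * s
    cbind(cos(phi) * X[, 1] - sin(phi) * X[, 2],
          sin(phi) * X[, 1] + cos(phi) * X[, 2])
  }
  sc_rot <- compute_strains(analytic_trajectories(rot), c(0, 0))
  expect_lt(max(abs(sc_rot$ecc), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(sc_rot$err), na.rm = TRUE), 1e-9)

  # uniform scale r = 0.9 R: Ecc = Err = 100*(0.81-1)/2 everywhere
  scl <- function(X, s) (1 + (0.9 - 1) * s) * X
  sc_s <- compute_strains(analytic_trajectories(scl), c(0, 0))
  expect_equal(mean(sc_s$ecc[, 5], na.rm = TRUE), -9.5, tolerance = 1e-6)
  expect_equal(mean(sc_s$err[, 5], na.rm = TRUE), -9.5, tolerance = 1e-6)
  expect_lt(diff(range(sc_s$ecc[, 5], na.rm = TRUE)), 1e-6)
})

test_that("peak metrics implement the signed extrema and strain rates", {
  tt <- seq(0, 600, by = 30)
  ecc <- -15 * sin(pi * tt / 600)
  curves <- make_strain_curves(matrix(rep(ecc, each = 6), 6),
                               angles = (1:6 - 0.5) * 60, frame_times = tt)
  pm <- peak_metrics(curves)
  expect_equal(pm$peak_ecc, -15, tolerance = 1e-9)
  # calculus oracle: d/dt[-15 sin(pi t/0.6 s)] has extrema +/- 15*pi/0.6
  expect_equal(pm$sr_systolic, -15 * pi / 0.6, tolerance = 0.05 * 78.5)
  expect_equal(pm$sr_diastolic, 15 * pi / 0.6, tolerance = 0.05 * 78.5)
  # time-axis rescaling by 2 halves strain rates, leaves peaks unchanged
  curves2 <- make_strain_curves(matrix(rep(ecc, each = 6), 6),
                                angles = (1:6 - 0.5) * 60,
                                frame_times = 2 * tt)
  pm2 <- peak_metrics(curves2)
  expect_equal(pm2$peak_ecc, pm$peak_ecc, tolerance = 1e-12)
  expect_equal(pm2$sr_systolic, pm$sr_systolic / 2, tolerance = 1e-9)
  # monotone decreasing curve peaks at the final frame
  mono <- make_strain_curves(matrix(rep(-seq(0, 10, length.out = 21),
                                        each = 6), 6),
                             angles = (1:6 - 0.5) * 60, frame_times = tt)
  expect_equal(peak_metrics(mono)$peak_ecc, -10)
  # all-invalid curves yield NA, not zeros
  nac <- make_strain_curves(matrix(NA_real_, 6, 21),
                            angles = (1:6 - 0.5) * 60, frame_times = tt)
  expect_true(is.na(peak_metrics(nac)$peak_ecc))
})

test_that("cross-correlation delays resolve shifts and are shift-invariant", {
  tt <- seq(0, 600, by = 30)
  base <- -15 * sin(pi * pmin(pmax(tt, 0), 600) / 600)^2
  shift_curve <- function(d) -15 * sin(pi * pmin(pmax(tt - d, 0), 600) / 600)^2
  ang <- rep((1:6 - 0.5) * 60, each = 10)
  # identical curves: all delays zero
  ecc0 <- matrix(rep(base, each = 60), 60)
  d0 <- segmental_delays(make_strain_curves(ecc0, ang, tt))
  expect_true(all(abs(d0$segment_delays$delay_ms) < 1e-6))
  # half the elements delayed by one frame (30 ms)
  ecc1 <- rbind(matrix(rep(base, each = 30), 30),
                matrix(rep(shift_curve(30), each = 30), 30))
  d1 <- segmental_delays(make_strain_curves(ecc1, ang, tt))
  sd1 <- d1$segment_delays$delay_ms
  expect_equal(sd1[4:6] - sd1[1:3], rep(30, 3), tolerance = 5)
  # adding a common shift to every element leaves delay differences intact
  ecc2 <- rbind(matrix(rep(shift_curve(60), each = 30), 30),
                matrix(rep(shift_curve(90), each = 30), 30))
  d2 <- segmental_delays(make_strain_curves(ecc2, ang, tt))
  sd2 <- d2$segment_delays$delay_ms
  expect_equal(sd2[4:6] - sd2[1:3], sd1[4:6] - sd1[1:3], tolerance = 2)
  # missing required slices flag the analysis incomplete
  dinc <- segmental_delays(list(basal = make_strain_curves(ecc0, ang, tt)),
                           required_slices = c("basal", "mid", "apical"))
  expect_false(dinc$complete)
  expect_true(is.na(dyssynchrony_summary(dinc)$global))
})

test_that("dyssynchrony index equals the periodic-spline + SD statistic", {
  ang <- (1:6 - 0.5) * 60
  # all delays equal -> DI = 0; uniform additive delay leaves DI unchanged
  expect_equal(dyssynchrony_index(rep(12, 6), ang), 0, tolerance = 1e-12)
  d <- c(0, 10, 20, 10, 0, -10)
  expect_equal(dyssynchrony_index(d, ang), dyssynchrony_index(d + 25, ang),
               tolerance = 1e-9)
  # independent dense-grid oracle via a periodic interpolation spline from
  # the splines package
  ps <- splines::periodicSpline(ang, d, period = 360)
  grid <- ang[1] + (0:359) * 360 / 360
  sm <- predict(ps, grid)$y
  oracle <- sqrt(mean((sm - mean(sm))^2))
  expect_equal(dyssynchrony_index(d, ang), oracle, tolerance = 1e-6)
  expect_gte(dyssynchrony_index(d, ang), 0)
  # fewer than 4 segments: NA with a warning
  expect_warning(na_di <- dyssynchrony_index(c(1, 2, 3), c(60, 180, 300)),
                 "fewer than 4")
  expect_true(is.na(na_di))
})
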