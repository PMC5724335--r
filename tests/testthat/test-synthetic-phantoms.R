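test_that("phantom specs reject non-physical values with the field named", {
  expect_error(molli_phantom_spec(annulus_inner_radius = 30,
                                  annulus_outer_radius = 20),
               "annulus_inner_radius")
  expect_error(molli_phantom_spec(t1_myocardium = c(pre = -5, post = 400)),
               "t1_myocardium")
  expect_error(molli_phantom_spec(inversion_times = c(100, 200, 300)),
               "inversion_times")
  expect_error(molli_phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(dense_phantom_spec(encoding_frequency = 0),
               "encoding_frequency")
  expect_error(dense_phantom_spec(n_frames = 2), "n_frames")
  expect_error(dense_phantom_spec(segment_delays = c(0, NA, 0)),
               "segment_delays")
  expect_error(dense_phantom_spec(
    deformation_law = list(type = "translation", dx = 1, dy = 0),
    segment_delays = c(0, 0, 0, 30, 30, 30)), "radial")
})

test_that("generators are bit-identical under a fixed seed", {
  sp <- molli_phantom_spec(grid_size = 32L, annulus_inner_radius = 18,
                           annulus_outer_radius = 26, noise_sd = 3,
                           seed = 7L)
  expect_identical(generate_molli_phantom(sp), generate_molli_phantom(sp))
  dsp <- dense_phantom_spec(grid_size = 32L, annulus_inner_radius = 8,
                            annulus_outer_radius = 13,
                            deformation_law = list(
                              type = "incompressible-annulus", delta = -15),
                            noise_sd_phase = 0.1, seed = 7L)
  expect_identical(generate_dense_phantom(dsp), generate_dense_phantom(dsp))
  csp <- cohort_sim_spec(n_subjects = 10L, true_beta = 0.4, seed = 7L)
  expect_identical(generate_cohort(csp), generate_cohort(csp))
})

test_that("noiseless inversion-recovery phantom round-trips T1 exactly", {
  sp <- molli_phantom_spec(noise_sd = 0, inversion_efficiency = 1,
                           t1_myocardium = c(pre = 950, post = 414))
  ph <- generate_molli_phantom(sp)
  idx <- which(ph$mask == 1L)[c(1, 50, 200)]
  sig <- matrix(ph$pre, ncol = length(ph$inversion_times))[idx, ]
  fit <- fit_t1(sig, ph$inversion_times)
  expect_true(all(fit$valid))
  expect_equal(fit$t1, rep(950, 3), tolerance = 1e-6)
})

test_that("blood T1 phantom feeds the configured hematocrit map", {
  sp <- molli_phantom_spec(noise_sd = 0, t1_blood = c(pre = 1600, post = 300))
  ph <- generate_molli_phantom(sp)
  idx <- which(ph$mask == 2L)[1]
  sig <- matrix(ph$pre, ncol = length(ph$inversion_times))[idx, ]
  t1b <- fit_t1(sig, ph$inversion_times)$t1
  # independent arithmetic on the configured default coefficients
  expect_equal(synthetic_hematocrit(t1b), 866.0 / 1600 - 0.1232,
               tolerance = 1e-6)
})

test_that("dense phantom phase and ground truth follow the encoding model", {
  # translation: strain identically zero, phase = wrap(2*pi*ke*u)
  sp <- dense_phantom_spec(grid_size = 80, n_frames = 11,
                           deformation_law = list(type = "translation",
                                                  dx = 3, dy = 0))
  ph <- generate_dense_phantom(sp)
  expect_true(all(ph$truth$ecc == 0) && all(ph$truth$err == 0))
  # at peak activation (mid-cine frame) displacement is exactly 3 mm
  px <- which(abs((1:80) - 40.5 - 30) < 0.6)[1]   # pixel near (30, 0)
  expect_equal(ph$phase_x[px, 40, 6], wrap_phase(2 * pi * 0.10 * 3),
               tolerance = 1e-9)
  expect_equal(wrap_phase(0.6 * pi), 0.6 * pi)

  # rotation: rigid, zero ground-truth strain
  spr <- dense_phantom_spec(grid_size = 64, annulus_inner_radius = 15,
                            annulus_outer_radius = 24,
                            deformation_law = list(type = "rotation",
                                                   angle = 20))
  phr <- generate_dense_phantom(spr)
  expect_true(all(phr$truth$ecc == 0) && all(phr$truth$err == 0))

  # uniform scale: closed form (k^2-1)/2 at peak
  sps <- dense_phantom_spec(grid_size = 96, n_frames = 11,
                            deformation_law = list(type = "uniform-scale",
                                                   scale = 0.9))
  phs <- generate_dense_phantom(sps)
  expect_equal(unname(phs$truth$ecc[, 6]),
               rep(100 * (0.9^2 - 1) / 2, nrow(phs$truth$ecc)),
               tolerance = 1e-9)

  # incompressible annulus: Ecc(R, t) = ((R^2+d)/R^2 - 1)/2, independently
  # evaluated here from the spec parameters
  spi <- dense_phantom_spec(grid_size = 96, n_frames = 11,
                            deformation_law = list(
                              type = "incompressible-annulus", delta = -120))
  phi <- generate_dense_phantom(spi)
  R <- phi$truth$ref_radius
  tt <- phi$frame_times
  s <- sin(pi * tt[6] / max(tt))^2
  oracle <- 100 * ((R^2 - 120 * s) / R^2 - 1) / 2
  expect_equal(unname(phi$truth$ecc[, 6]), unname(oracle), tolerance = 1e-9)
})

test_that("infeasible deformations raise an unwrapping-feasibility warning", {
  sp <- dense_phantom_spec(grid_size = 64, n_frames = 3,
                           annulus_inner_radius = 15,
                           annulus_outer_radius = 24,
                           deformation_law = list(type = "translation",
                                                  dx = 14, dy = 0))
  expect_warning(generate_dense_phantom(sp), "feasibility")
})

test_that("cohort simulator reproduces its generating model", {
  # noiseless limit: fitted standardized beta = 1
  sp0 <- cohort_sim_spec(n_subjects = 40, true_beta = 1, age_effect = 0,
                         sex_effect = 0, region_effects = c(0, 0, 0),
                         residual_sd = 1e-4, seed = 11L)
  tab0 <- generate_cohort(sp0)
  fit0 <- fit_mixed_model(tab0, "regional")
  expect_equal(fit0$beta, 1, tolerance = 1e-3)

  # exchangeable residual correlation is recovered empirically
  spc <- cohort_sim_spec(n_subjects = 400, levels = "segmental",
                         true_beta = 0, age_effect = 0, sex_effect = 0,
                         region_effects = rep(0, 16),
                         within_subject_correlation = 0.5,
                         residual_sd = 1, seed = 12L)
  tabc <- generate_cohort(spc)
  y <- matrix(tabc$outcome, nrow = 16)   # levels x subjects
  cors <- cor(t(y))
  emp <- mean(cors[upper.tri(cors)])
  expect_equal(emp, 0.5, tolerance = 0.05)

  # Monte-Carlo outcome means converge to the model-implied means
  spm <- cohort_sim_spec(n_subjects = 2000, true_beta = 0.3,
                         region_effects = c(-0.3, 0, 0.3), seed = 13L)
  tabm <- generate_cohort(spm)
  means <- tapply(tabm$outcome, tabm$level, mean)
  sem <- tapply(tabm$outcome, tabm$level, sd) / sqrt(2000)
  implied <- c(-0.3, 0, 0.3)
  expect_true(all(abs(means - implied) < 3 * sem))

  # invalid correlation rejected
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(cohort_sim_spec(within_subject_correlation = bad),
               "positive-definite")
})
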