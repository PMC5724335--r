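make_table <- function(pred, out, n_levels = 3) {
  n <- length(pred) / n_levels
  data.frame(subject = rep(sprintf("S%02d", seq_len(n)), each = n_levels),
             level = factor(rep(c("basal", "mid", "apical")[seq_len(n_levels)],
                                n)),
             predictor = pred, outcome = out,
             age = rep(seq(20, 40, length.out = n), each = n_levels),
             sex = rep(rep(c("male", "female"), length.out = n),
                       each = n_levels))
}

test_that("variable preparation standardizes and transforms correctly", {
  tab <- make_table(rep(c(1, 2, 3), 4), rep(c(1, 2, 3), 4))
  prep <- prepare_variables(tab)
  expect_equal(mean(prep$predictor_z), 0, tolerance = 1e-12)
  expect_equal(sd(prep$predictor_z), 1, tolerance = 1e-12)
  expect_true(all(prep$male %in% 0:1))
  expect_equal(mean(prep$outcome_z), 0, tolerance = 1e-12)
  expect_equal(sd(prep$outcome_z), 1, tolerance = 1e-12)
  # column {1,2,3}: z-scores {-1, 0, 1} (one record per subject)
  tab3 <- make_table(c(1, 2, 3), c(1, 2, 3), n_levels = 1)
  expect_equal(prepare_variables(tab3)$outcome_z, c(-1, 0, 1))
  # log policy: {e, e^2, e^3} -> {-1, 0, 1}
  tabl <- make_table(c(1, 2, 3), exp(c(1, 2, 3)), n_levels = 1)
  expect_equal(prepare_variables(tabl, log_outcome = TRUE)$outcome_z,
               c(-1, 0, 1))
  # degenerate and invalid inputs
  expect_error(prepare_variables(make_table(c(1, 2, 3), c(5, 5, 5),
                                            n_levels = 1)),
               "zero")
  tabneg <- make_table(c(1, 2, 3), c(1, -2, 3), n_levels = 1)
  expect_error(prepare_variables(tabneg, log_outcome = TRUE), "S02")
})

test_that("standardized beta is unit-invariant and exact in the noiseless limit", {
  sp <- cohort_sim_spec(n_subjects = 40, true_beta = 0.5, seed = 21L)
  tab <- generate_cohort(sp)
  f0 <- fit_mixed_model(tab, "regional")
  # affine rescaling of predictor or outcome units leaves beta unchanged
  tab2 <- tab
  tab2$predictor <- 100 * tab2$predictor + 7
  tab2$outcome <- 0.01 * tab2$outcome - 3
  f2 <- fit_mixed_model(tab2, "regional")
  expect_equal(f2$beta, f0$beta, tolerance = 1e-8)
  expect_equal(f2$p, f0$p, tolerance = 1e-6)
  # segmental (exchangeable) path
  sps <- cohort_sim_spec(n_subjects = 30, levels = "segmental",
                         true_beta = 0.4, seed = 22L)
  fs <- fit_mixed_model(generate_cohort(sps), "segmental")
  expect_equal(fs$structure, "exchangeable")
  expect_equal(fs$beta, 0.4, tolerance = 0.15)
})

test_that("BH step-up flags match brute-force enumeration", {
  # hand-evaluated examples
  expect_equal(bh_adjust(c(0.01, 0.03, 0.04)), rep(TRUE, 3))
  expect_equal(bh_adjust(c(0.02, 0.2, 0.9)), rep(FALSE, 3))
  expect_equal(bh_adjust(rep(0.01, 5)), rep(TRUE, 5))
  # property: 1000 random p-vectors against an independent brute-force
  # evaluation of the step-up definition
  brute <- function(p, alpha = 0.05) {
    m <- length(p)
    ps <- sort(p)
    k <- 0
    for (j in seq_len(m)) if (ps[j] <= j * alpha / m) k <- j
    if (k == 0) rep(FALSE, m) else p <= ps[k]
  }
  set.seed(99)
  for (i in 1:1000) {
    m <- sample(1:12, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    expect_identical(bh_adjust(p), brute(p))
  }
  # cross-check against the adjusted-p formulation
  set.seed(100)
  p <- runif(20)^2
  expect_identical(bh_adjust(p), p.adjust(p, "BH") <= 0.05)
})

test_that("Pearson correlation and p-value match the exact t-test", {
  expect_equal(pearson_with_p(1:5, 1:5)$r, 1)
  expect_equal(pearson_with_p(1:5, -(1:5))$r, -1)
  ex <- pearson_with_p(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(ex$r, 0.6, tolerance = 1e-12)
  set.seed(3)
  x <- rnorm(25); y <- 0.4 * x + rnorm(25)
  ours <- pearson_with_p(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_with_p(rep(1, 5), 1:5), "variance")
})

test_that("z-scores use the configured reference constants", {
  ref <- data.frame(measure = c("lv_edvi", "lv_edvi"),
                    sex = c("male", "female"),
                    mean = c(80, 70), sd = c(12, 10))
  expect_equal(zscore_against_reference(80, "lv_edvi", "male", ref), 0)
  expect_equal(zscore_against_reference(80 + 24, "lv_edvi", "male", ref), 2)
  # same value, different sex key, different z
  expect_false(zscore_against_reference(85, "lv_edvi", "male", ref) ==
                 zscore_against_reference(85, "lv_edvi", "female", ref))
  expect_error(zscore_against_reference(80, "rv_edvi", "male", ref),
               "no reference")
})

test_that("reproducibility statistics match hand computations exactly", {
  # CoV: pairs (10,12), (20,18) -> (sqrt(2)+sqrt(2))/30 = 9.43%
  expect_equal(mean_cov(c(10, 20), c(12, 18)), 100 * 2 * sqrt(2) / 30,
               tolerance = 1e-12)
  expect_equal(mean_cov(c(5, 7, 9), c(5, 7, 9)), 0)
  # scale invariance
  expect_equal(mean_cov(3 * c(10, 20), 3 * c(12, 18)),
               mean_cov(c(10, 20), c(12, 18)), tolerance = 1e-12)
  # Bland-Altman: differences {1,-1} -> bias 0, limits +/- 1.96*sqrt(2)
  ba <- bland_altman(c(1, 0), c(0, 1))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_upper, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_lower, -1.96 * sqrt(2), tolerance = 1e-12)
  # constant offset: bias 2, zero-width limits
  ba2 <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$loa_upper - ba2$loa_lower, 0)
  # identical observers
  ba3 <- bland_altman(c(1, 2), c(1, 2))
  expect_equal(unlist(ba3[c("bias", "loa_lower", "loa_upper")]),
               c(bias = 0, loa_lower = 0, loa_upper = 0))
})

test_that("correlation power analysis is exact and monotone", {
  n80 <- min_n_correlation(rho = 0.30, alpha = 0.05, power = 0.80)
  n90 <- min_n_correlation(rho = 0.30, alpha = 0.05, power = 0.90)
  expect_gt(n90, n80)
  expect_equal(attr(n80, "method"), "exact")
  nf <- min_n_correlation(rho = 0.30, method = "fisher-z")
  expect_equal(attr(nf, "method"), "fisher-z")
  # the boundary property: power crosses the target exactly at n
  expect_gte(correlation_power(n80, 0.30), 0.80)
  expect_lt(correlation_power(n80 - 1, 0.30), 0.80)

  # simulation oracle at rho = 0.5: rejection rate crosses 0.80 at the
  # returned n and falls below at n - 1
  n5 <- as.integer(min_n_correlation(rho = 0.50, alpha = 0.05, power = 0.80))
  rej_rate <- function(n, reps = 20000) {
    set.seed(7)
    tc <- qt(0.975, n - 2)
    hits <- 0L
    for (i in seq_len(reps)) {
      x <- rnorm(n)
      y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
      r <- cor(x, y)
      t <- r * sqrt((n - 2) / (1 - r^2))
      if (abs(t) > tc) hits <- hits + 1L
    }
    hits / reps
  }
  expect_gte(rej_rate(n5), 0.80 - 0.01)
  expect_lt(rej_rate(n5 - 1L), 0.80 + 0.005)
})
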