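test_that("sample sizes hit the classic benchmarks", {
  expect_equal(sample_size(0.5), 64L)   # the canonical medium-effect answer
  expect_equal(sample_size(0.2), 394L)
  expect_equal(sample_size(10), 2L)     # floor at 2 per group
  expect_error(sample_size(0), "d")
  expect_error(sample_size(-1), "d")
})

test_that("noncentral-t sizing agrees with stats::power.t.test", {
  for (d in seq(0.15, 1.4, by = 0.05)) {
    n_cont <- stats::power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                  power = 0.8, strict = TRUE)$n
    expect_equal(sample_size(d), as.integer(ceiling(n_cont - 1e-9)))
  }
  # and the power function itself matches at integer n
  p_ours <- power_two_sample_t(64, 0.5)
  p_ref <- stats::power.t.test(n = 64, delta = 0.5, sd = 1,
                               sig.level = 0.05, strict = TRUE)$power
  expect_equal(p_ours, p_ref, tolerance = 1e-9)
})

test_that("Monte-Carlo power matches the analytic power function", {
  set.seed(314)
  mc <- mc_power_two_sample_t(64, 0.5, nrep = 20000)
  expect_lt(abs(mc - power_two_sample_t(64, 0.5)), 3 * sqrt(0.8 * 0.2 / 20000))
})

test_that("the efficacy model scales the natural course", {
  curve <- reference_curve(sy_x = 24)
  expect_equal(treated_mean(curve, 60, efficacy = 1), 0)
  expect_equal(treated_mean(curve, 60, efficacy = 0), predict(curve, day = 60))
  expect_equal(treated_mean(curve, 60, efficacy = 0.6),
               0.4 * (46.2 * exp(-0.6) - 55.7))
  expect_error(treated_mean(curve, 60, efficacy = 1.2), "efficacy")
})

test_that("Cohen's d is the efficacy-scaled loss over sigma", {
  curve <- reference_curve(sy_x = 24)
  expect_equal(cohens_d(curve, 60, efficacy = 0), 0)
  # a 12%-point effect against sigma 24 is the textbook d = 0.5
  flat <- decay_fit(y0 = -12, plateau = -12, k = 0, sy_x = 24)
  expect_equal(cohens_d(flat, 100, efficacy = 1), 0.5)
  expect_equal(cohens_d(curve, 60, efficacy = 0.4),
               0.4 * abs(46.2 * exp(-0.6) - 55.7) / 24)
  nosigma <- reference_curve()
  expect_error(cohens_d(nosigma, 60, 0.5), "sigma")
  expect_error(cohens_d(decay_fit(-9.5, -55.7, 0.01, sy_x = 0), 60, 0.5),
               "sigma")
})

test_that("d is linear in efficacy and n nonincreasing in d", {
  curve <- reference_curve(sy_x = 24)
  d1 <- cohens_d(curve, 90, 0.4)
  d2 <- cohens_d(curve, 90, 0.8)
  expect_equal(d2, 2 * d1)
  ds <- seq(0.2, 2, by = 0.1)
  ns <- sample_size(ds)
  expect_true(all(diff(ns) <= 0))
})

test_that("a 1x1 grid equals the scalar pipeline", {
  curve <- reference_curve(sy_x = 24)
  g <- build_grid(curve, durations = 60, efficacies = 0.6)
  expect_equal(nrow(g), 1)
  expect_equal(g$placebo_pct, predict(curve, day = 60))
  expect_equal(g$treated_pct, treated_mean(curve, 60, 0.6))
  expect_equal(g$cohens_d, cohens_d(curve, 60, 0.6))
  expect_equal(g$n_per_group, sample_size(cohens_d(curve, 60, 0.6)))
})

test_that("the grid is monotone in duration and efficacy", {
  curve <- reference_curve(sy_x = 24)
  g <- build_grid(curve)
  m <- matrix(g$n_per_group, nrow = 4)  # durations x efficacies
  expect_true(all(apply(m, 2, diff) <= 0))  # longer trial, fewer patients
  expect_true(all(apply(m, 1, diff) <= 0))  # stronger drug, fewer patients
  expect_true(all(m[, 5] == apply(m, 1, min)))  # efficacy 1 is each row's min
})

test_that("sigma calibration recovers a known generating sigma", {
  curve <- reference_curve()
  ref <- build_grid(curve, sigma = 24)
  m <- matrix(ref$n_per_group, nrow = 4,
              dimnames = list(c("30", "60", "90", "180"),
                              c("0.2", "0.4", "0.6", "0.8", "1")))
  expect_lt(abs(calibrate_sigma(curve, reference = m) - 24), 0.3)
})

test_that("leave-one-out calibration never sees the held-out cell", {
  curve <- reference_curve()
  ref <- published_sample_sizes()
  # corrupt one cell grossly; excluding it must restore the clean answer
  ref_bad <- ref; ref_bad["60", "0.6"] <- 400L
  s_clean <- calibrate_sigma(curve, d_digits = 2)
  s_loo <- calibrate_sigma(curve, reference = ref_bad,
                           leave_out = c(60, 0.6), d_digits = 2)
  expect_equal(s_loo, s_clean)
  expect_false(isTRUE(all.equal(
    calibrate_sigma(curve, reference = ref_bad, d_digits = 2), s_clean)))
})
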