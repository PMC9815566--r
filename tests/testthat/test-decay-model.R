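truth_y0 <- -9.5; truth_pl <- -55.7; truth_k <- 0.01

test_that("noiseless series are recovered to high precision", {
  days <- seq(0, 1040, by = 30)
  pct <- (truth_y0 - truth_pl) * exp(-truth_k * days) + truth_pl
  fit <- fit_decay(days, pct)
  cf <- coef(fit)
  expect_lt(abs(cf[["y0"]] / truth_y0 - 1), 1e-6)
  expect_lt(abs(cf[["plateau"]] / truth_pl - 1), 1e-6)
  expect_lt(abs(cf[["k"]] / truth_k - 1), 1e-6)
  expect_lt(fit$sy_x, 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("a constant series collapses to the k = 0 limit", {
  fit <- fit_decay(c(0, 100, 400, 900), rep(-20, 4))
  cf <- coef(fit)
  expect_equal(cf[["k"]], 0)
  expect_equal(cf[["y0"]], -20)
  expect_equal(cf[["plateau"]], -20)
  expect_equal(fit$sy_x, 0)
  expect_true(is.na(fit$r2))  # SST = 0: R^2 undefined, reported as such
})

test_that("prediction evaluates the fitted curve", {
  curve <- reference_curve()
  expect_equal(predict(curve, day = 0), -9.5)
  expect_equal(predict(curve, day = 60), 46.2 * exp(-0.6) - 55.7)
  expect_equal(predict(curve, day = 60), -30.3449, tolerance = 1e-4)
  expect_equal(predict(curve, day = 1e8), -55.7)  # asymptote
  expect_error(predict(curve, day = -1), "day")
})

test_that("prediction decreases monotonically toward the plateau when k > 0", {
  curve <- reference_curve()
  days <- seq(0, 2000, by = 10)
  p <- predict(curve, day = days)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > -55.7))
})

test_that("goodness of fit separates signal from a constant mean", {
  days <- seq(0, 1040, by = 30)
  exact <- fit_decay(days, predict(reference_curve(), day = days))
  g <- goodness_of_fit(exact)
  expect_equal(g$r2, 1, tolerance = 1e-10)
  expect_equal(g$p_vs_constant, 0)

  flat <- fit_decay(c(0, 100, 400, 900), rep(-20, 4))
  gf <- goodness_of_fit(flat)
  expect_true(is.na(gf$r2))
  expect_equal(gf$p_vs_constant, 1)

  # the study regime: 38 scans, noise SD 24 -> modest but significant fit
  sim <- simulate(reference_curve(sy_x = 24), seed = 401,
                  days = round(seq(0, 1040, length.out = 38)))[[1]]
  noisy <- fit_decay(sim)
  gn <- goodness_of_fit(noisy)
  expect_gt(gn$r2, 0.1)
  expect_lt(gn$r2, 0.7)
  expect_lt(gn$p_vs_constant, 0.05)
})

test_that("the fit is invariant to the order of the points", {
  set.seed(70)
  sim <- simulate(reference_curve(sy_x = 15), seed = 7,
                  days = sample(0:1040, 60))[[1]]
  f1 <- fit_decay(sim)
  f2 <- fit_decay(sim[sample(nrow(sim)), ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
})

test_that("the NLS objective is at least locally optimal", {
  sse <- function(par, d) {
    sum((d$pct_change - ((par[1] - par[2]) * exp(-par[3] * d$day) + par[2]))^2)
  }
  for (s in 1:20) {
    set.seed(100 + s)
    sim <- simulate(reference_curve(sy_x = 15), seed = 1000 + s,
                    days = sample(0:1040, 40))[[1]]
    fit <- fit_decay(sim)
    expect_lte(sse(coef(fit), sim),
               sse(c(truth_y0, truth_pl, truth_k), sim) + 1e-8)
  }
})

test_that("a brute-force grid search never beats the NLS objective", {
  sse <- function(y0, pl, k, d) {
    sum((d$pct_change - ((y0 - pl) * exp(-k * d$day) + pl))^2)
  }
  y0_grid <- seq(-40, 20, by = 4)
  pl_grid <- seq(-90, -20, by = 4)
  k_grid <- c(0, 10^seq(-4, -1, length.out = 12))
  for (s in 1:20) {
    set.seed(200 + s)
    sim <- simulate(reference_curve(sy_x = 20), seed = 2000 + s,
                    days = sample(0:1040, 12))[[1]]
    fit <- fit_decay(sim)
    grid_best <- min(sapply(y0_grid, function(a) {
      min(sapply(pl_grid, function(b) {
        min(sapply(k_grid, function(kk) sse(a, b, kk, sim)))
      }))
    }))
    expect_lte(sse(coef(fit)[1], coef(fit)[2], coef(fit)[3], sim),
               grid_best + 1e-8)
  }
})

test_that("estimates land within sampling error of the generating truth", {
  set.seed(770)
  sim <- simulate(reference_curve(sy_x = 24), seed = 77,
                  days = sample(0:1040, 500, replace = TRUE))[[1]]
  fit <- fit_decay(sim)
  cf <- coef(fit)
  expect_lt(abs(cf[["y0"]] - truth_y0), 4 * fit$se[["y0"]])
  expect_lt(abs(cf[["plateau"]] - truth_pl), 4 * fit$se[["plateau"]])
  expect_lt(abs(cf[["k"]] - truth_k), 4 * fit$se[["k"]])
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(fit_decay(c(10, 10, 10, 10), c(-1, -2, -3, -4)), "degenerate")
  expect_error(fit_decay(c(0, 10, 20), c(-1, -2, -3)), "at least 4")
  expect_error(fit_decay(data.frame(day = 1:4)), "missing column")
})

test_that("simulate() is reproducible and leaves the RNG alone", {
  curve <- reference_curve(sy_x = 24)
  set.seed(1); before <- .Random.seed
  a <- simulate(curve, nsim = 2, seed = 5, days = 0:50)
  expect_identical(.Random.seed, before)
  b <- simulate(curve, nsim = 2, seed = 5, days = 0:50)
  expect_identical(a, b)
  expect_false(identical(a[[1]]$pct_change, a[[2]]$pct_change))
})
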