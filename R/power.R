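#' Power of the two-sided two-sample t-test
#'
#' Exact power via the noncentral t distribution: with `n` subjects per
#' group and standardized effect `d`, the test statistic has `2n - 2`
#' degrees of freedom and noncentrality \eqn{d\sqrt{n/2}}; power is the
#' probability that |T| exceeds the two-sided critical value.
#'
#' @param n Subjects per group (>= 2). Vectorised.
#' @param d Cohen's d (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @examples
#' power_two_sample_t(64, d = 0.5)  # ~0.80, the classic medium-effect anchor
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05) {
  if (any(n < 2)) stop("`n` must be >= 2 per group", call. = FALSE)
  check_scalar_number(d, "d")
  check_scalar_number(alpha, "alpha", min = 0, max = 1)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Minimum per-group sample size for a two-sample t-test
#'
#' Smallest integer `n` per group such that the two-sided two-sample t-test
#' at level `alpha` reaches the target power for effect size `d`, found by
#' iterating the noncentral-t power function (monotone in `n`, so a doubling
#' search bracketing the target followed by bisection). Floored at n = 2.
#'
#' @param d Cohen's d, > 0. Vectorised.
#' @param alpha Two-sided significance level, default 0.05.
#' @param power Target power, default 0.8.
#' @return Integer subjects per group.
#' @examples
#' sample_size(0.5)  # 64 per group
#' sample_size(0.2)  # 394
#' @export
sample_size <- function(d, alpha = 0.05, power = 0.8) {
  check_scalar_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  check_scalar_number(power, "power", min = 1e-12, max = 1 - 1e-12)
  vapply(d, function(d1) {
    if (!is.finite(d1) || d1 <= 0) stop("`d` must be > 0", call. = FALSE)
    if (power_two_sample_t(2, d1, alpha) >= power) return(2L)
    lo <- 2; hi <- 4
    while (power_two_sample_t(hi, d1, alpha) < power) {
      lo <- hi; hi <- hi * 2
      if (hi > 1e7) stop("required n exceeds 1e7; effect too small",
                         call. = FALSE)
    }
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (power_two_sample_t(mid, d1, alpha) >= power) hi <- mid else lo <- mid
    }
    as.integer(hi)
  }, integer(1))
}

#' Projected treated-arm mean percent change under a drug efficacy
#'
#' The efficacy model: a drug of efficacy `e` scales the natural-course
#' percent change at the trial endpoint by `(1 - e)` — a 100%-effective
#' neuroprotectant abolishes all GCL loss, a 0%-effective one leaves the
#' natural course untouched.
#'
#' @param fit A `decay_fit` (fitted or constructed via [decay_fit()]).
#' @param day Trial duration in days (endpoint), > 0.
#' @param efficacy Fraction in [0, 1].
#' @return Projected treated-arm mean percent change.
#' @examples
#' curve <- decay_fit(-9.5, -55.7, 0.01)
#' treated_mean(curve, day = 60, efficacy = 0.6)
#' @export
treated_mean <- function(fit, day, efficacy) {
  check_efficacy(efficacy)
  (1 - efficacy) * predict(fit, day = day)
}

check_efficacy <- function(efficacy) {
  if (any(!is.finite(efficacy)) || any(efficacy < 0) || any(efficacy > 1)) {
    stop("`efficacy` must lie in [0, 1]", call. = FALSE)
  }
  invisible(efficacy)
}

#' Cohen's d for a placebo-vs-treated contrast at a trial endpoint
#'
#' Standardized difference between the natural-course (placebo) mean percent
#' change and the `(1 - e)`-scaled treated mean, using the regression's
#' residual standard deviation as the common within-group SD:
#' \deqn{d = e \cdot |\hat y(day)| / \sigma.}
#'
#' @param fit A `decay_fit`.
#' @param day Trial duration in days.
#' @param efficacy Fraction in [0, 1]. Vectorised (as is `day`).
#' @param sigma Within-group SD in percent units; defaults to the fit's
#'   `sy_x`. Must be > 0.
#' @return Cohen's d (dimensionless, >= 0).
#' @export
cohens_d <- function(fit, day, efficacy, sigma = NULL) {
  check_efficacy(efficacy)
  if (is.null(sigma)) sigma <- fit$sy_x
  if (is.na(sigma) || sigma <= 0) {
    stop("`sigma` must be > 0 (a zero residual SD gives an infinite d)",
         call. = FALSE)
  }
  efficacy * abs(predict(fit, day = day)) / sigma
}

#' Effect-size and sample-size grid over trial durations and drug efficacies
#'
#' Builds the full Cartesian planning grid from a fitted decay course: for
#' every (duration, efficacy) cell the projected placebo and treated mean
#' percent changes, Cohen's d, and the minimum per-group sample size from
#' [sample_size()].
#'
#' `d_digits` optionally rounds Cohen's d before the sample-size lookup.
#' Effect sizes in planning tables are conventionally reported to two
#' decimals, and sizing from the rounded value reproduces published tables
#' built that way; the default (`NULL`) uses full precision.
#'
#' @param fit A `decay_fit`.
#' @param durations Trial durations in days.
#' @param efficacies Drug efficacies, fractions in [0, 1].
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param sigma Within-group SD (percent); defaults to the fit's `sy_x`. See
#'   [calibrate_sigma()] for reconstructing an unreported sigma from a
#'   published grid.
#' @param d_digits Round Cohen's d to this many decimals before sizing;
#'   `NULL` for no rounding.
#' @return A data frame of class `sample_size_grid` with columns
#'   `trial_days`, `efficacy`, `placebo_pct`, `treated_pct`, `cohens_d`,
#'   `n_per_group`; attributes `alpha`, `power`, `sigma`, `d_digits`.
#' @examples
#' curve <- decay_fit(-9.5, -55.7, 0.01, sy_x = 24.2)
#' build_grid(curve, durations = c(60, 90), efficacies = c(0.6, 1.0))
#' @export
build_grid <- function(fit, durations = c(30, 60, 90, 180),
                       efficacies = seq(0.2, 1, by = 0.2),
                       alpha = 0.05, power = 0.8, sigma = NULL,
                       d_digits = NULL) {
  if (isFALSE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (length(durations) == 0 || length(efficacies) == 0) {
    stop("`durations` and `efficacies` must be nonempty", call. = FALSE)
  }
  if (any(durations <= 0)) stop("`trial_days` must be > 0", call. = FALSE)
  check_efficacy(efficacies)
  if (is.null(sigma)) sigma <- fit$sy_x
  grid <- expand.grid(trial_days = durations, efficacy = efficacies,
                      KEEP.OUT.ATTRS = FALSE)
  grid$placebo_pct <- predict(fit, day = grid$trial_days)
  grid$treated_pct <- (1 - grid$efficacy) * grid$placebo_pct
  d <- cohens_d(fit, grid$trial_days, grid$efficacy, sigma = sigma)
  if (!is.null(d_digits)) d <- round(d, d_digits)
  grid$cohens_d <- d
  grid$n_per_group <- ifelse(grid$cohens_d > 0,
                             sample_size(pmax(grid$cohens_d, 1e-12),
                                         alpha, power),
                             NA_integer_)
  structure(grid, alpha = alpha, power = power, sigma = sigma,
            d_digits = d_digits,
            class = c("sample_size_grid", "data.frame"))
}

#' @export
print.sample_size_grid <- function(x, ...) {
  wide <- stats::xtabs(n_per_group ~ trial_days + efficacy, data = x)
  cat(sprintf(
    "Minimum patients per group (two-sided t-test, alpha = %g, power = %g, sigma = %.3g%%)\n",
    attr(x, "alpha"), attr(x, "power"), attr(x, "sigma")))
  cat("rows: trial duration (days); columns: drug efficacy\n")
  m <- as.matrix(wide)
  dimnames(m) <- list(paste0(rownames(wide), " d"),
                      paste0(as.numeric(colnames(wide)) * 100, "%"))
  print(m)
  invisible(x)
}

#' Published minimum sample sizes for a BRAO neuroprotection trial
#'
#' The published 4 x 5 planning table this package's grid builder
#' reconstructs: minimum patients per group to detect a protective effect on
#' GCL loss, by trial duration (rows, days) and drug efficacy (columns), at
#' alpha 0.05 and power 0.8. Used as the calibration reference for
#' [calibrate_sigma()] when the residual SD behind a published table is not
#' itself reported.
#'
#' @return Integer matrix, durations x efficacies, with dimnames.
#' @export
published_sample_sizes <- function() {
  m <- matrix(c(486L, 130L, 57L, 33L, 21L,
                253L,  64L, 29L, 17L, 11L,
                165L,  44L, 20L, 12L,  8L,
                100L,  26L, 12L,  8L,  6L),
              nrow = 4, byrow = TRUE,
              dimnames = list(trial_days = c("30", "60", "90", "180"),
                              efficacy = c("0.2", "0.4", "0.6", "0.8", "1")))
  m
}

#' Calibrate the residual SD against a published sample-size grid
#'
#' When a published planning table was computed from a residual SD that was
#' itself never printed, sigma can be reconstructed: choose the sigma whose
#' reconstructed grid matches the published cell counts best in least
#' squares. The objective is piecewise constant in sigma (sample sizes are
#' integers), so the search is a deterministic scan over a fine grid of
#' candidate values; ties resolve to the middle of the optimal plateau.
#'
#' `leave_out` excludes one cell from the objective — used when that cell is
#' itself the quantity under test, so the calibration never sees it.
#'
#' @param fit A `decay_fit` describing the natural course.
#' @param reference Published grid: an integer matrix shaped like
#'   [published_sample_sizes()] with numeric dimnames (durations in days,
#'   efficacies as fractions).
#' @param leave_out `NULL`, or `c(trial_days, efficacy)` naming the cell to
#'   exclude.
#' @param d_digits Passed to [build_grid()]: round d before sizing (set 2 to
#'   mirror tables built from two-decimal effect sizes).
#' @param alpha,power Test settings of the published grid.
#' @param candidates Candidate sigma values to scan (percent units).
#' @return The calibrated sigma (percent units).
#' @examples
#' curve <- decay_fit(-9.5, -55.7, 0.01)
#' calibrate_sigma(curve, d_digits = 2)  # ~24.2
#' @export
calibrate_sigma <- function(fit, reference = published_sample_sizes(),
                            leave_out = NULL, d_digits = NULL,
                            alpha = 0.05, power = 0.8,
                            candidates = seq(15, 35, by = 0.01)) {
  durations <- as.numeric(rownames(reference))
  efficacies <- as.numeric(colnames(reference))
  if (anyNA(durations) || anyNA(efficacies)) {
    stop("`reference` needs numeric dimnames (days, efficacy fractions)",
         call. = FALSE)
  }
  w <- matrix(1, nrow(reference), ncol(reference))
  if (!is.null(leave_out)) {
    i <- match(leave_out[1], durations)
    j <- match(leave_out[2], efficacies)
    if (is.na(i) || is.na(j)) {
      stop("`leave_out` cell not found in reference grid", call. = FALSE)
    }
    w[i, j] <- 0
  }
  sse <- vapply(candidates, function(s) {
    g <- build_grid(fit, durations, efficacies, alpha, power, sigma = s,
                    d_digits = d_digits)
    m <- matrix(g$n_per_group, nrow = length(durations))
    sum(w * (m - reference)^2)
  }, numeric(1))
  best <- which(sse == min(sse))
  candidates[best[ceiling(length(best) / 2)]]
}

#' Monte-Carlo power of the two-sample t-test
#'
#' Brute-force simulation oracle for [power_two_sample_t()] /
#' [sample_size()]: draws `nrep` pairs of normal samples with standardized
#' mean difference `d` and reports the rejection rate of the two-sided
#' two-sample t-test at level `alpha`. Pooled-variance t statistics are
#' computed vectorised, in chunks, so large replicate counts stay within
#' memory.
#'
#' @param n Subjects per group.
#' @param d True standardized mean difference.
#' @param alpha Two-sided level.
#' @param nrep Simulation replicates.
#' @param chunk Replicates per vectorised block.
#' @return Estimated power (rejection proportion).
#' @export
mc_power_two_sample_t <- function(n, d, alpha = 0.05, nrep = 50000,
                                  chunk = 10000) {
  stopifnot(n >= 2)
  tcrit <- stats::qt(1 - alpha / 2, 2 * n - 2)
  rejected <- 0
  done <- 0
  while (done < nrep) {
    m <- min(chunk, nrep - done)
    x <- matrix(stats::rnorm(n * m, mean = d), nrow = n)
    y <- matrix(stats::rnorm(n * m), nrow = n)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- (colSums(x^2) - n * mx^2) / (n - 1)
    vy <- (colSums(y^2) - n * my^2) / (n - 1)
    tstat <- (mx - my) / sqrt((vx + vy) / n)
    rejected <- rejected + sum(abs(tstat) > tcrit)
    done <- done + m
  }
  rejected / nrep
}
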