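test_that("the same seed reproduces a cohort byte-identically", {
  a <- simulate_cohort(cohort_params(n_patients = 5, seed = 11))
  b <- simulate_cohort(cohort_params(n_patients = 5, seed = 11))
  c <- simulate_cohort(cohort_params(n_patients = 5, seed = 12))
  expect_identical(a$records, b$records)
  expect_identical(a$ledger, b$ledger)
  expect_false(identical(a$records, c$records))
})

test_that("cohort generation leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_cohort(cohort_params(n_patients = 2, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("a noiseless day-0 scan embeds exactly the true y0", {
  p <- cohort_params(n_patients = 1, scans_per_patient = c(1, 1),
                     day_range = c(0, 0), noise_sd = 0,
                     unaffected_noise_sd = 0, seed = 2)
  coh <- simulate_cohort(p)
  expect_equal(coh$ledger$realized_pct, -9.5)
  # and the percent change recomputed from raw thicknesses agrees
  led <- coh$ledger
  rec <- coh$records
  aff <- rec[rec$status == "affected" & rec$quadrant == led$quadrant &
               rec$layer == "GCL", ]
  ref <- rec[rec$status == "reference" & rec$quadrant == led$quadrant &
               rec$layer == "GCL", ]
  expect_equal(percent_change(aff$thickness_um, ref$thickness_um), -9.5)
})

test_that("k = 0 collapses the decay to a constant at y0", {
  p <- cohort_params(n_patients = 4, scans_per_patient = c(3, 3),
                     true_y0 = -20, true_plateau = -20, true_k = 0,
                     noise_sd = 0, unaffected_noise_sd = 0, seed = 8)
  coh <- simulate_cohort(p)
  expect_equal(coh$ledger$true_pct, rep(-20, nrow(coh$ledger)))
  expect_equal(coh$ledger$realized_pct, rep(-20, nrow(coh$ledger)))
})

test_that("invalid parameters are rejected naming the offending field", {
  expect_error(cohort_params(n_patients = 0), "n_patients")
  expect_error(cohort_params(noise_sd = -1), "noise_sd")
  expect_error(cohort_params(true_k = -0.01), "true_k")
  expect_error(cohort_params(true_y0 = -60, true_plateau = -10),
               "true_plateau")
  expect_error(cohort_params(day_range = c(100, 0)), "day_range")
  expect_error(cohort_params(affected_quadrant = "Q"), "affected_quadrant")
})

test_that("unaffected quadrants of the affected eye scatter around 0%", {
  p <- cohort_params(n_patients = 40, scans_per_patient = c(2, 2),
                     unaffected_noise_sd = 1.5, seed = 21)
  coh <- simulate_cohort(p)
  rec <- coh$records
  lesion <- coh$ledger[!duplicated(coh$ledger$patient_id),
                       c("patient_id", "quadrant")]
  pcs <- unlist(lapply(seq_len(nrow(lesion)), function(i) {
    pid <- lesion$patient_id[i]
    pr <- rec[rec$patient_id == pid & rec$layer == "GCL" &
                rec$quadrant != lesion$quadrant[i], ]
    aff <- pr[pr$status == "affected", ]
    ref <- pr[pr$status == "reference", ]
    key <- paste(aff$day, aff$quadrant)
    ref <- ref[match(key, paste(ref$day, ref$quadrant)), ]
    percent_change(aff$thickness_um, ref$thickness_um)
  }))
  expect_gt(length(pcs), 100)
  se <- sd(pcs) / sqrt(length(pcs))
  expect_lt(abs(mean(pcs)), 3 * se)
})

test_that("mean generated change at a fixed day converges to the curve", {
  day <- 60
  p <- cohort_params(n_patients = 300, scans_per_patient = c(1, 1),
                     day_range = c(day, day), noise_sd = 24, seed = 31)
  coh <- simulate_cohort(p)
  truth <- (-9.5 + 55.7) * exp(-0.01 * day) - 55.7
  se <- sd(coh$ledger$realized_pct) / sqrt(nrow(coh$ledger))
  expect_lt(abs(mean(coh$ledger$realized_pct) - truth), 3 * se)
})

test_that("default cohort matches the study's longitudinal structure", {
  coh <- simulate_cohort(cohort_params(seed = 4))
  expect_equal(length(unique(coh$ledger$patient_id)), 17)
  scans <- table(coh$ledger$patient_id)
  expect_true(all(scans >= 1 & scans <= 5))
  expect_true(all(coh$ledger$day >= 0 & coh$ledger$day <= 1040))
  # expected total scan count is ~38; any one draw should be in a sane band
  expect_gt(nrow(coh$ledger), 17)
  expect_lt(nrow(coh$ledger), 70)
  # records cover both eyes, 4 quadrants, all profile layers
  expect_setequal(unique(coh$records$quadrant), quadrant_codes())
  expect_setequal(unique(coh$records$layer), spectralis_layers())
})
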