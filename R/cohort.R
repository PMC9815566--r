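#' Parameters for the synthetic BRAO cohort generator
#'
#' Bundles and validates every setting of [simulate_cohort()]. The defaults
#' mirror the longitudinal structure of a small retrospective BRAO series:
#' 17 patients contributing 1-5 scans each over days 0-1040 after occlusion
#' onset, with the affected quadrant's GCL following a single-phase decay
#' from -9.5% at onset toward a -55.7% plateau at rate 0.01/day, and
#' residual scatter of 24 percent-units around the curve.
#'
#' @param n_patients Number of patients, >= 1.
#' @param scans_per_patient Integer interval `c(min, max)` of scans per
#'   patient.
#' @param scan_weights Sampling weights for the scan counts
#'   `scans_per_patient[1]:scans_per_patient[2]`. For the default 1-5 range
#'   the default weights decline with count (follow-up attrition), giving an
#'   expected 2.25 scans/patient — about 38 scans from 17 patients, the
#'   typical yield of a small retrospective series; for other ranges the
#'   default is uniform.
#' @param day_range Closed interval of scan days, default `c(0, 1040)`.
#' @param true_y0 True percent change at day 0 (<= 0).
#' @param true_plateau True asymptotic percent change (<= `true_y0`).
#' @param true_k True per-day decay constant, >= 0.
#' @param noise_sd Residual scatter of the affected cell on the percent
#'   scale, >= 0.
#' @param between_patient_sd_k SD of per-patient decay-rate heterogeneity
#'   (per day); 0 disables it. Per-patient rates are truncated at 0.
#' @param unaffected_noise_sd Measurement repeatability applied (on the
#'   percent scale) to every affected-eye cell other than the tracked one,
#'   so unaffected quadrants scatter around 0% change; 0 makes the affected
#'   eye an exact copy of the reference outside the lesion.
#' @param normative A [normative_profile()] to draw baseline thicknesses
#'   from.
#' @param affected_quadrant `"random"` (one quadrant drawn per patient) or a
#'   fixed quadrant code.
#' @param schedule `"uniform"` scan days, or `"early_weighted"` (half the
#'   scans within the first 100 days, mirroring denser early follow-up).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 17L,
                          scans_per_patient = c(1L, 5L),
                          scan_weights = NULL,
                          day_range = c(0L, 1040L),
                          true_y0 = -9.5,
                          true_plateau = -55.7,
                          true_k = 0.01,
                          noise_sd = 24,
                          between_patient_sd_k = 0,
                          unaffected_noise_sd = 1,
                          normative = normative_profile(),
                          affected_quadrant = "random",
                          schedule = c("uniform", "early_weighted"),
                          seed = 1L) {
  check_scalar_number(n_patients, "n_patients", min = 1)
  if (length(scans_per_patient) != 2 || any(scans_per_patient < 1) ||
      scans_per_patient[1] > scans_per_patient[2]) {
    stop_field("scans_per_patient", "must be an interval c(min, max), min >= 1")
  }
  n_counts <- scans_per_patient[2] - scans_per_patient[1] + 1
  if (is.null(scan_weights)) {
    scan_weights <- if (identical(as.integer(scans_per_patient), c(1L, 5L))) {
      c(0.4, 0.25, 0.15, 0.1, 0.1)
    } else {
      rep(1, n_counts)
    }
  }
  if (length(scan_weights) != n_counts || any(scan_weights < 0) ||
      sum(scan_weights) <= 0) {
    stop_field("scan_weights",
               "must be nonnegative weights, one per possible scan count")
  }
  if (length(day_range) != 2 || any(day_range < 0) ||
      day_range[1] > day_range[2]) {
    stop_field("day_range", "must be a nonempty interval of days >= 0")
  }
  check_scalar_number(true_y0, "true_y0", max = 0)
  check_scalar_number(true_plateau, "true_plateau", max = 0)
  if (true_plateau > true_y0) {
    stop_field("true_plateau", "must be <= true_y0 for a loss process")
  }
  check_scalar_number(true_k, "true_k", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(between_patient_sd_k, "between_patient_sd_k", min = 0)
  check_scalar_number(unaffected_noise_sd, "unaffected_noise_sd", min = 0)
  if (!inherits(normative, "normative_profile")) {
    stop_field("normative", "must be a normative_profile()")
  }
  if (!identical(affected_quadrant, "random") &&
      !affected_quadrant %in% quadrant_codes()) {
    stop_field("affected_quadrant", "must be \"random\" or a quadrant code")
  }
  schedule <- match.arg(schedule)
  check_scalar_number(seed, "seed")
  structure(
    list(n_patients = as.integer(n_patients),
         scans_per_patient = as.integer(scans_per_patient),
         scan_weights = scan_weights,
         day_range = as.integer(day_range),
         true_y0 = true_y0, true_plateau = true_plateau, true_k = true_k,
         noise_sd = noise_sd, between_patient_sd_k = between_patient_sd_k,
         unaffected_noise_sd = unaffected_noise_sd,
         normative = normative, affected_quadrant = affected_quadrant,
         schedule = schedule, seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' Generate a synthetic longitudinal OCT cohort with known ground truth
#'
#' Emulates the data structure the pipeline consumes. For each patient: a
#' healthy reference eye whose per-(quadrant, layer) thicknesses are drawn
#' once from the normative profile (stable across visits); an affected eye
#' identical to it except that the lesioned quadrant's GCL thickness at each
#' scan equals reference x (1 + pct/100), where pct is the true decay curve
#' value at that day plus Gaussian noise (`noise_sd`, on the percent scale).
#' Other affected-eye cells get independent percent-scale jitter of
#' `unaffected_noise_sd`. Scan days are sampled without replacement within
#' `day_range`. Realized percent change is floored at -99.9 so back-computed
#' thicknesses stay positive.
#'
#' Output is deterministic for a fixed `params$seed` and leaves the caller's
#' RNG state untouched.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `brao_cohort`:
#'   \describe{
#'     \item{records}{Thickness records in the [read_thickness()] schema,
#'       both eyes, all quadrants and profile layers, inner 3 mm ring.}
#'     \item{ledger}{Ground truth per scan: `patient_id`, `day`, `quadrant`
#'       (lesioned), `true_pct` (noiseless curve value), `realized_pct`
#'       (value embedded in the affected GCL record), `true_k` (per-patient
#'       rate).}
#'     \item{params}{The generating parameters.}
#'   }
#' @examples
#' coh <- simulate_cohort(cohort_params(n_patients = 2, seed = 7))
#' head(coh$ledger)
#' @export
simulate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("`params` must be created by cohort_params()", call. = FALSE)
  }
  with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  prof <- p$normative
  layers <- unique(prof$layer)
  quads <- quadrant_codes()
  n_days_avail <- p$day_range[2] - p$day_range[1] + 1L

  rec_list <- vector("list", p$n_patients)
  led_list <- vector("list", p$n_patients)
  for (i in seq_len(p$n_patients)) {
    pid <- sprintf("P%03d", i)
    n_scans <- if (p$scans_per_patient[1] == p$scans_per_patient[2]) {
      p$scans_per_patient[1]
    } else {
      sample(seq(p$scans_per_patient[1], p$scans_per_patient[2]), 1,
             prob = p$scan_weights)
    }
    n_scans <- min(n_scans, n_days_avail)
    days <- sort(sample_days(n_scans, p$day_range, p$schedule))
    aff_eye <- sample(eye_codes(), 1)
    ref_eye <- setdiff(eye_codes(), aff_eye)
    lesion_q <- if (identical(p$affected_quadrant, "random")) {
      sample(quads, 1)
    } else {
      p$affected_quadrant
    }
    k_i <- max(0, p$true_k + if (p$between_patient_sd_k > 0) {
      stats::rnorm(1, sd = p$between_patient_sd_k)
    } else 0)

    # baseline thickness per (quadrant, layer), shared by both eyes
    base <- prof
    base$thickness_um <- pmax(
      stats::rnorm(nrow(prof), prof$mean_um, prof$sd_um), 1)

    true_pct <- decay_curve_value(days, p$true_y0, p$true_plateau, k_i)
    realized <- true_pct + if (p$noise_sd > 0) {
      stats::rnorm(n_scans, sd = p$noise_sd)
    } else 0
    realized <- pmax(realized, -99.9)

    cell_n <- nrow(base)
    per_visit <- function(d, scan_idx) {
      ref <- data.frame(patient_id = pid, eye = ref_eye,
                        status = "reference", day = d, ring = "inner_3mm",
                        quadrant = base$quadrant, layer = base$layer,
                        thickness_um = base$thickness_um)
      aff_th <- base$thickness_um
      if (p$unaffected_noise_sd > 0) {
        jit <- stats::rnorm(cell_n, sd = p$unaffected_noise_sd)
        aff_th <- aff_th * pmax(1 + jit / 100, 0.001)
      }
      lesion <- base$quadrant == lesion_q & base$layer == "GCL"
      aff_th[lesion] <- base$thickness_um[lesion] *
        (1 + realized[scan_idx] / 100)
      aff <- data.frame(patient_id = pid, eye = aff_eye,
                        status = "affected", day = d, ring = "inner_3mm",
                        quadrant = base$quadrant, layer = base$layer,
                        thickness_um = aff_th)
      rbind(aff, ref)
    }
    rec_list[[i]] <- do.call(rbind, Map(per_visit, days, seq_along(days)))
    led_list[[i]] <- data.frame(patient_id = pid, day = days,
                                quadrant = lesion_q, true_pct = true_pct,
                                realized_pct = realized, true_k = k_i)
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  ledger <- do.call(rbind, led_list)
  rownames(ledger) <- NULL
  structure(list(records = records, ledger = ledger, params = p),
            class = "brao_cohort")
}

# Sample `n` distinct integer scan days from `range`. "early_weighted" puts
# about half the scans in the first 100 days, mimicking denser early
# follow-up after an acute event.
sample_days <- function(n, range, schedule) {
  all_days <- seq(range[1], range[2])
  if (schedule == "early_weighted" && length(all_days) > 1) {
    cut <- range[1] + 100
    w <- ifelse(all_days <= cut, 1 / max(sum(all_days <= cut), 1),
                1 / max(sum(all_days > cut), 1))
    all_days[sample.int(length(all_days), n, prob = w)]
  } else {
    # sample.int avoids sample()'s scalar-x surprise when the range is one day
    all_days[sample.int(length(all_days), n)]
  }
}

#' @export
print.brao_cohort <- function(x, ...) {
  cat(sprintf("Synthetic BRAO cohort: %d patients, %d scans, days %d-%d\n",
              x$params$n_patients, nrow(x$ledger),
              min(x$ledger$day), max(x$ledger$day)))
  cat(sprintf("truth: y0 = %g, plateau = %g, k = %g, noise SD = %g\n",
              x$params$true_y0, x$params$true_plateau, x$params$true_k,
              x$params$noise_sd))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the thickness records CSV (the [read_thickness()] schema) and the
#' ground-truth ledger CSV side by side.
#'
#' @param cohort A `brao_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "brao_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_path <- file.path(dir, "thickness.csv")
  led_path <- file.path(dir, "ground_truth.csv")
  write_thickness(cohort$records, rec_path)
  utils::write.csv(cohort$ledger, led_path, row.names = FALSE, quote = FALSE)
  invisible(c(records = rec_path, ledger = led_path))
}
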