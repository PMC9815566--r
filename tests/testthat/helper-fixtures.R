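# Shared fixtures, built in code.

# The reference natural-course decay curve used throughout the tests:
# -9.5% at onset decaying at 0.01/day toward a -55.7% plateau.
reference_curve <- function(sy_x = NA_real_) {
  decay_fit(y0 = -9.5, plateau = -55.7, k = 0.01, sy_x = sy_x)
}

# One patient's GCL records on the inner ring: affected-eye thicknesses
# realise the requested percent changes against a 50 um fellow eye.
# `pct` is named by quadrant; `days` gives the scan schedule (the same
# percent changes are reused at every day unless `pct` is a matrix with one
# row per day).
make_patient_records <- function(pid = "P1",
                                 pct = c(T = -5, S = -31, N = -8, I = -2),
                                 days = 10, ref_um = 50, fellow = TRUE,
                                 fellow_quadrants = quadrant_codes()) {
  if (!is.matrix(pct)) {
    pct <- matrix(rep(pct, each = length(days)), nrow = length(days),
                  dimnames = list(NULL, names(pct)))
  }
  rows <- list()
  for (i in seq_along(days)) {
    for (q in colnames(pct)) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, eye = "OD", status = "affected", day = days[i],
        ring = "inner_3mm", quadrant = q, layer = "GCL",
        thickness_um = ref_um * (1 + pct[i, q] / 100))
    }
    if (fellow) {
      for (q in fellow_quadrants) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pid, eye = "OS", status = "reference", day = days[i],
          ring = "inner_3mm", quadrant = q, layer = "GCL",
          thickness_um = ref_um)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Small GCL-only normative profile to keep fixtures light.
gcl_profile <- function(mean_um = 48, sd_um = 4) {
  normative_profile(layers = "GCL", means = c(GCL = mean_um),
                    sds = c(GCL = sd_um))
}
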