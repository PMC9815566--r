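#' Percent thickness change of an affected eye against its reference
#'
#' The study statistic: \deqn{\%\,change = -1 \cdot (1 - A/R) \cdot 100}
#' where \eqn{A} is the affected-eye thickness and \eqn{R} the reference
#' (fellow-eye or normative) thickness, both in micrometers. Negative values
#' mean thinning; 0 means no change; \eqn{-100} means total loss. Thickening
#' (\eqn{A > R}) yields positive values and is retained, not clipped —
#' measurement noise makes it inevitable and censoring it would bias fits.
#'
#' @param affected_um Affected-eye thickness, micrometers, >= 0. Vectorised.
#' @param reference_um Reference thickness, micrometers, > 0. Vectorised.
#' @return Percent change (numeric), same length as the inputs.
#' @examples
#' percent_change(24, 48)   # -50: half the reference thickness
#' percent_change(50, 50)   #   0
#' percent_change(0, 40)    # -100: total loss
#' @export
percent_change <- function(affected_um, reference_um) {
  if (any(!is.finite(reference_um)) || any(reference_um <= 0)) {
    stop("`reference_um` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(affected_um)) || any(affected_um < 0)) {
    stop("`affected_um` must be finite and >= 0", call. = FALSE)
  }
  -1 * (1 - affected_um / reference_um) * 100
}

#' Assemble longitudinal percent-change series from thickness records
#'
#' For each patient the affected-eye thickness in the tracked (quadrant,
#' layer, ring) cell is converted to percent change against that patient's
#' reference (fellow eye when present, otherwise the normative profile; see
#' [select_reference()]), one point per scan day. Points are never averaged
#' within a day: each scan is one regression observation.
#'
#' By default the tracked quadrant is chosen per patient as the most affected
#' quadrant at the earliest scan ([most_affected_quadrant()]) and held fixed
#' across follow-ups; pass `quadrant` to override.
#'
#' @param records Thickness records (data frame in the [read_thickness()]
#'   schema).
#' @param normative Optional [normative_profile()] fallback for patients with
#'   no fellow eye.
#' @param layer Tracked layer, default `"GCL"`.
#' @param ring Tracked ring, default `"inner_3mm"`.
#' @param quadrant Fixed quadrant code, or `NULL` to auto-select per patient.
#' @param mode `"aggregate"` pools all patients into one series;
#'   `"per_patient"` returns a named list of per-patient series.
#' @return A data frame of class `pct_series` with columns `patient_id`,
#'   `day`, `pct_change` (aggregate mode), or a named list of such data
#'   frames (per-patient mode). Attributes `layer`, `ring` and `quadrant`
#'   record the tracked cell.
#' @export
build_series <- function(records, normative = NULL, layer = "GCL",
                         ring = "inner_3mm", quadrant = NULL,
                         mode = c("aggregate", "per_patient")) {
  mode <- match.arg(mode)
  validate_records(records)
  records <- records[records$ring == ring, , drop = FALSE]
  pats <- unique(records$patient_id[records$status == "affected"])
  if (length(pats) == 0) stop("no affected-eye records in selection",
                              call. = FALSE)

  one_patient <- function(pid) {
    prec <- records[records$patient_id == pid, , drop = FALSE]
    quad <- if (is.null(quadrant)) {
      most_affected_quadrant(prec, normative = normative, layer = layer,
                             ring = ring)
    } else {
      match.arg(quadrant, quadrant_codes())
    }
    ref <- select_reference(prec, normative = normative, layers = layer,
                            ring = ring)
    ref_um <- ref$reference_um[ref$quadrant == quad & ref$layer == layer]
    if (length(ref_um) != 1) {
      stop(sprintf("no reference value for patient %s quadrant %s layer %s",
                   pid, quad, layer), call. = FALSE)
    }
    aff <- prec[prec$status == "affected" & prec$quadrant == quad &
                  prec$layer == layer, , drop = FALSE]
    if (nrow(aff) == 0) {
      stop(sprintf("no affected-eye records for patient %s in %s/%s",
                   pid, quad, layer), call. = FALSE)
    }
    aff <- aff[order(aff$day), , drop = FALSE]
    data.frame(patient_id = aff$patient_id, day = aff$day,
               pct_change = percent_change(aff$thickness_um, ref_um),
               quadrant = quad, row.names = NULL)
  }

  per <- lapply(pats, one_patient)
  names(per) <- pats
  decorate <- function(df, quad) {
    structure(df, layer = layer, ring = ring, quadrant = quad,
              class = c("pct_series", "data.frame"))
  }
  if (mode == "per_patient") {
    return(lapply(per, function(df) {
      decorate(df[c("patient_id", "day", "pct_change")], df$quadrant[1])
    }))
  }
  pooled <- do.call(rbind, per)
  quads <- unique(pooled$quadrant)
  decorate(pooled[c("patient_id", "day", "pct_change")],
           if (length(quads) == 1) quads else quads)
}
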