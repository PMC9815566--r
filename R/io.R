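#' Read and write quadrant-resolved layer-thickness tables
#'
#' The tabular interchange format is a UTF-8 CSV with header
#' `patient_id,eye,status,day,ring,quadrant,layer,thickness_um`: one row per
#' (patient, eye, visit day, ring, quadrant, layer) thickness measurement in
#' micrometers. `eye` is OD/OS, `status` is affected/reference/normative,
#' `day` is integer days since occlusion onset, `ring`/`quadrant`/`layer`
#' come from the closed vocabularies ([quadrant_codes()],
#' [spectralis_layers()], [ring_codes()]).
#'
#' Every row is validated; violations (missing column, unknown code,
#' nonpositive thickness, negative day, duplicate key) raise an error naming
#' the offending file row.
#'
#' @param path Path to a CSV file.
#' @param records Data frame of thickness records to write.
#' @return `read_thickness()`: a validated data frame of records.
#'   `write_thickness()`: the path, invisibly.
#' @export
read_thickness <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(thickness_columns(), names(raw))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  raw <- raw[thickness_columns()]
  raw$day <- suppressWarnings(as.integer(raw$day))
  raw$thickness_um <- suppressWarnings(as.numeric(raw$thickness_um))
  validate_records(raw, row_offset = 1L)  # header is file line 1
  raw
}

#' @rdname read_thickness
#' @export
write_thickness <- function(records, path) {
  validate_records(records)
  utils::write.csv(records[thickness_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Validate a record data frame against the schema invariants. `row_offset`
# shifts reported row numbers to file line numbers.
validate_records <- function(records, row_offset = 0L) {
  if (!is.data.frame(records)) stop("records must be a data frame",
                                    call. = FALSE)
  miss <- setdiff(thickness_columns(), names(records))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond)) + row_offset
      stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
                   paste(utils::head(rows, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad_row(!records$eye %in% eye_codes(), "unknown eye code")
  bad_row(!records$status %in% status_codes(), "unknown status code")
  bad_row(!records$ring %in% ring_codes(), "unknown ring code")
  bad_row(!records$quadrant %in% quadrant_codes(), "unknown quadrant code")
  bad_row(!records$layer %in% spectralis_layers(), "unknown layer code")
  bad_row(!is.finite(records$day) | records$day < 0, "day must be >= 0")
  bad_row(!is.finite(records$thickness_um) | records$thickness_um <= 0,
          "thickness must be > 0")
  key <- do.call(paste, c(records[c("patient_id", "eye", "day", "ring",
                                    "quadrant", "layer")], sep = "\r"))
  bad_row(duplicated(key), "duplicate (patient, eye, day, ring, quadrant, layer) key")
  invisible(records)
}

#' Reference thickness per quadrant and layer for one patient
#'
#' Returns the thickness the affected eye is compared against, cell by cell:
#' the healthy fellow eye when the patient has one (its mean across visits),
#' otherwise the quadrant-specific normative mean. Sources are never mixed
#' within one (quadrant, layer) cell, and the chosen source is reported.
#'
#' @param records One patient's thickness records.
#' @param normative Optional [normative_profile()] fallback.
#' @param layers Layers to resolve (default all present in the records).
#' @param ring Ring to resolve, default `"inner_3mm"`.
#' @return Data frame with columns `quadrant`, `layer`, `reference_um`,
#'   `source` (`"fellow"` or `"normative"`).
#' @export
select_reference <- function(records, normative = NULL, layers = NULL,
                             ring = "inner_3mm") {
  validate_records(records)
  if (length(unique(records$patient_id)) != 1) {
    stop("records must belong to a single patient", call. = FALSE)
  }
  records <- records[records$ring == ring, , drop = FALSE]
  if (!any(records$status == "affected")) {
    stop("patient has no affected-eye records", call. = FALSE)
  }
  if (is.null(layers)) layers <- unique(records$layer)
  fellow <- records[records$status == "reference", , drop = FALSE]
  cells <- expand.grid(quadrant = quadrant_codes(), layer = layers,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    q <- cells$quadrant[i]; l <- cells$layer[i]
    f <- fellow[fellow$quadrant == q & fellow$layer == l, , drop = FALSE]
    if (nrow(f) > 0) {
      return(data.frame(quadrant = q, layer = l,
                        reference_um = mean(f$thickness_um),
                        source = "fellow"))
    }
    if (!is.null(normative)) {
      row <- normative_lookup(normative, q, l)
      if (!is.null(row)) {
        return(data.frame(quadrant = q, layer = l,
                          reference_um = row$mean_um, source = "normative"))
      }
    }
    data.frame(quadrant = q, layer = l, reference_um = NA_real_,
               source = NA_character_)
  })
  out <- do.call(rbind, out)
  # only demand resolvable cells where the affected eye was measured
  aff <- records[records$status == "affected", c("quadrant", "layer")]
  needed <- unique(aff[aff$layer %in% layers, , drop = FALSE])
  if (nrow(needed) > 0) {
    chk <- merge(needed, out, by = c("quadrant", "layer"))
    if (anyNA(chk$reference_um)) {
      bad <- chk[is.na(chk$reference_um), ]
      stop(sprintf("no fellow-eye or normative reference for %s",
                   paste(paste(bad$quadrant, bad$layer, sep = "/"),
                         collapse = ", ")), call. = FALSE)
    }
  }
  out[!is.na(out$reference_um), , drop = FALSE]
}

#' Most affected quadrant at the earliest scan
#'
#' Identifies the quadrant to follow over time: the one with the most
#' negative percent change (largest relative loss) in the given layer at the
#' patient's earliest affected-eye scan. The quadrant is then held fixed
#' across follow-ups by the series builder — re-selecting per visit would
#' confound the time series. Ties break deterministically in the order
#' T < S < N < I. The result does not depend on row order of the input.
#'
#' @param records One patient's thickness records.
#' @param normative Optional [normative_profile()] fallback for the
#'   reference.
#' @param layer Layer to rank by, default `"GCL"`.
#' @param ring Ring, default `"inner_3mm"`.
#' @return A quadrant code (`"T"`, `"S"`, `"N"` or `"I"`).
#' @examples
#' # A patient whose superior quadrant lost 31% reads back "S".
#' @export
most_affected_quadrant <- function(records, normative = NULL, layer = "GCL",
                                   ring = "inner_3mm") {
  validate_records(records)
  records <- records[records$ring == ring, , drop = FALSE]
  aff <- records[records$status == "affected" & records$layer == layer, ,
                 drop = FALSE]
  if (nrow(aff) == 0) {
    stop("no affected-eye records for layer ", layer, call. = FALSE)
  }
  first_day <- min(aff$day)
  aff <- aff[aff$day == first_day, , drop = FALSE]
  ref <- select_reference(records, normative = normative, layers = layer,
                          ring = ring)
  pc <- vapply(quadrant_codes(), function(q) {
    a <- aff$thickness_um[aff$quadrant == q]
    r <- ref$reference_um[ref$quadrant == q & ref$layer == layer]
    if (length(a) == 0 || length(r) != 1) return(NA_real_)
    percent_change(a[1], r)
  }, numeric(1))
  if (all(is.na(pc))) {
    stop("no quadrant with both affected and reference values at day ",
         first_day, call. = FALSE)
  }
  # which.min takes the first minimum: T < S < N < I tie-break for free
  quadrant_codes()[which.min(pc)]
}
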