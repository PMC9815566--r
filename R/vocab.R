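#' Closed vocabularies for the thickness data model
#'
#' Quadrants follow the ETDRS convention (temporal, superior, nasal,
#' inferior); the layer set defaults to the eleven Spectralis segmentation
#' outputs commonly reported on the 3 mm ring. Both are closed vocabularies:
#' records carrying other codes are rejected at read time.
#'
#' @return Character vectors of valid codes.
#' @examples
#' quadrant_codes()
#' spectralis_layers()
#' @export
quadrant_codes <- function() c("T", "S", "N", "I")

#' @rdname quadrant_codes
#' @export
spectralis_layers <- function() {
  c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL", "PR", "RPE", "IRL", "ORL", "RT")
}

#' @rdname quadrant_codes
#' @export
ring_codes <- function() c("inner_3mm", "outer_6mm")

#' @rdname quadrant_codes
#' @export
eye_codes <- function() c("OD", "OS")

#' @rdname quadrant_codes
#' @export
status_codes <- function() c("affected", "reference", "normative")

# Columns of the thickness CSV schema, in file order.
thickness_columns <- function() {
  c("patient_id", "eye", "status", "day", "ring", "quadrant", "layer",
    "thickness_um")
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (x < min) stop_field(field, sprintf("must be >= %s", min))
  if (x > max) stop_field(field, sprintf("must be <= %s", max))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
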