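#' Normative retinal layer thickness profile
#'
#' Per-(quadrant, layer) mean and SD thicknesses from a reference group of
#' healthy (non-occluded) eyes, used (a) as the reference when a patient has
#' no healthy fellow eye and (b) by the synthetic-cohort generator to draw
#' baseline thicknesses.
#'
#' The built-in default values are documented plumbing, not population ground
#' truth: plausible inner-ring magnitudes for each Spectralis layer (e.g. GCL
#' about 50 um in the 3 mm-ring quadrants) with SDs of roughly 8% of the
#' mean, identical across quadrants. Supply measured `means`/`sds` for real
#' analyses.
#'
#' @param layers Character vector of layer codes.
#' @param quadrants Character vector of quadrant codes.
#' @param means Named numeric vector of mean thicknesses (um) per layer, or a
#'   data frame with columns `quadrant`, `layer`, `mean_um` (and optionally
#'   `sd_um`) for quadrant-specific values. `NULL` uses the built-in
#'   defaults.
#' @param sds Named numeric vector of SDs (um) per layer; ignored when
#'   `means` is a data frame carrying `sd_um`. `NULL` defaults to 8% of each
#'   mean.
#' @param source_n Number of reference eyes the profile summarises (default
#'   9, the usual size of a small normative group).
#' @return Data frame of class `normative_profile` with columns `quadrant`,
#'   `layer`, `mean_um`, `sd_um`; attribute `source_n`.
#' @examples
#' prof <- normative_profile(layers = c("GCL", "RNFL"))
#' subset(prof, quadrant == "S")
#' @export
normative_profile <- function(layers = spectralis_layers(),
                              quadrants = quadrant_codes(),
                              means = NULL, sds = NULL, source_n = 9L) {
  if (!is.numeric(source_n) || length(source_n) != 1L || source_n < 1) {
    stop_field("source_n", "must be a count >= 1")
  }
  if (is.data.frame(means)) {
    need <- c("quadrant", "layer", "mean_um")
    if (!all(need %in% names(means))) {
      stop_field("means", "data frame needs quadrant, layer, mean_um columns")
    }
    prof <- means
    if (!"sd_um" %in% names(prof)) prof$sd_um <- 0.08 * prof$mean_um
  } else {
    defaults <- c(RNFL = 24, GCL = 50, IPL = 42, INL = 40, OPL = 32,
                  ONL = 70, PR = 80, RPE = 16, IRL = 156, ORL = 198, RT = 340)
    if (is.null(means)) {
      unknown <- setdiff(layers, names(defaults))
      if (length(unknown) > 0) {
        stop_field("means", paste("no default mean for layer(s):",
                                  paste(unknown, collapse = ", ")))
      }
      means <- defaults[layers]
    }
    if (is.null(names(means)) || !all(layers %in% names(means))) {
      stop_field("means", "must be named with an entry per layer")
    }
    if (is.null(sds)) sds <- 0.08 * means
    if (is.null(names(sds)) || !all(layers %in% names(sds))) {
      stop_field("sds", "must be named with an entry per layer")
    }
    prof <- expand.grid(quadrant = quadrants, layer = layers,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    prof$mean_um <- unname(means[prof$layer])
    prof$sd_um <- unname(sds[prof$layer])
  }
  if (any(prof$mean_um <= 0)) stop_field("means", "all means must be > 0")
  if (any(prof$sd_um < 0)) stop_field("sds", "all SDs must be >= 0")
  missing_cells <- nrow(expand.grid(quadrants, layers)) > nrow(unique(
    prof[c("quadrant", "layer")]))
  if (missing_cells) {
    stop_field("means", "profile must cover every quadrant x layer cell")
  }
  structure(prof[c("quadrant", "layer", "mean_um", "sd_um")],
            source_n = as.integer(source_n),
            class = c("normative_profile", "data.frame"))
}

# Look up one (quadrant, layer) cell; NULL if absent.
normative_lookup <- function(profile, quadrant, layer) {
  row <- profile[profile$quadrant == quadrant & profile$layer == layer, ,
                 drop = FALSE]
  if (nrow(row) == 0) NULL else row
}
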