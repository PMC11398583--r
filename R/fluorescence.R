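#' Maximum-intensity projection of a fluorescence z-stack
#'
#' @param stack A `fluor_stack` or a `(Z, Y, X)` array.
#' @return A `(Y, X)` matrix: the pixel-wise maximum over z.
#' @export
max_projection <- function(stack) {
  vol <- if (inherits(stack, "fluor_stack")) stack$volume else stack
  if (length(dim(vol)) != 3L) stop("expected a (Z, Y, X) array")
  apply(vol, c(2, 3), max)
}

#' Autofluorescence threshold from solvent-control worms
#'
#' Pools the in-mask pixel intensities of all control-well projections and
#' returns the 95th percentile: the intensity above which the brightest 5%
#' of control pixels lie. Quantiles use linear interpolation between order
#' statistics (type 7).
#'
#' @param control_projections List of max-projection matrices from control
#'   worms.
#' @param control_masks Matching list of `binary_mask` objects.
#' @return The threshold intensity (scalar).
#' @export
control_threshold <- function(control_projections, control_masks) {
  if (length(control_projections) != length(control_masks))
    stop("projections and masks must match")
  pool <- unlist(lapply(seq_along(control_projections), function(i) {
    m <- control_masks[[i]]
    g <- if (inherits(m, "binary_mask")) m$grid else m
    control_projections[[i]][g]
  }))
  if (length(pool) == 0L) stop("no in-mask control pixels to pool")
  unname(stats::quantile(pool, 0.95, type = 7))
}

#' Autofluorescence metrics for one worm
#'
#' Mean intensity of the in-mask pixels strictly above the control-derived
#' threshold, normalised per unit body length and per unit body area. If no
#' pixel exceeds the threshold all metrics are 0 and the record is flagged.
#'
#' @param projection Max-projection matrix of the worm's fluorescence stack.
#' @param mask The worm's `binary_mask` (same shape as the projection).
#' @param threshold Threshold from [control_threshold()].
#' @param length_um,area_um2 Body measures from the phenotype module.
#' @param integrate If `TRUE`, use the summed (integrated) above-threshold
#'   intensity instead of the mean as the numerator.
#' @return A list of class `af_record`: `threshold_intensity`,
#'   `mean_bright_intensity`, `per_unit_length`, `per_unit_area`,
#'   `n_bright_px`, `qc_flags`.
#' @export
af_metrics <- function(projection, mask, threshold, length_um, area_um2,
                       integrate = FALSE) {
  if (length_um <= 0 || area_um2 <= 0)
    stop("length and area must be positive")
  g <- if (inherits(mask, "binary_mask")) mask$grid else mask
  if (!all(dim(projection) == dim(g))) stop("projection and mask shapes differ")
  vals <- projection[g]
  bright <- vals[vals > threshold]  # strictly above
  qc <- character()
  if (length(bright) == 0L) {
    m <- 0
    qc <- "no_bright_pixels"
  } else {
    m <- if (integrate) sum(bright) else mean(bright)
  }
  structure(list(threshold_intensity = threshold,
                 mean_bright_intensity = m,
                 per_unit_length = m / length_um,
                 per_unit_area = m / area_um2,
                 n_bright_px = length(bright),
                 qc_flags = qc),
            class = "af_record")
}
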