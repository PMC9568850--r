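#' Extract the circumferential intensity profile at a radius
#'
#' Returns the angular intensity vector of the polar raster row nearest to
#' the requested radius. The full-circumference exclusion rule applies: if
#' any sample on that circumference is invalid (out of frame), the radius
#' cannot be measured and an error is raised.
#'
#' @param polar A `polar_image`.
#' @param radius_um Radius in micrometres.
#' @return An object of class `"profile"`: list with `radius_um` (the
#'   radius actually sampled) and `values` (length `n_angular`).
#' @export
extract_profile <- function(polar, radius_um) {
  stopifnot(inherits(polar, "polar_image"))
  px_um <- polar$calibration$pixel_size_um
  row <- round(radius_um / px_um) + 1
  if (row < 1 || row > nrow(polar$pixels)) {
    stop("incomplete circumference: radius ", radius_um,
         " um is beyond the polar raster", call. = FALSE)
  }
  values <- polar$pixels[row, ]
  if (anyNA(values)) {
    stop("incomplete circumference at radius ", radius_um, " um",
         call. = FALSE)
  }
  structure(list(radius_um = (row - 1) * px_um, values = values),
            class = "profile")
}

#' Convert angular FWHM detections to physical channel widths
#'
#' Maps each angular full-width at half-maximum through [arc_length_um()]
#' at its profile's radius, producing the per-detection channel width
#' table.
#'
#' @param detections Data frame with columns `radius_um`, `angle_px`,
#'   `fwhm_px`, `prominence` (as produced by [measure_radial_series()]).
#' @param polar The `polar_image` the detections came from (supplies
#'   `n_angular`).
#' @param biofilm_id,condition Labels stored alongside each detection.
#' @return A channel width table: data frame with columns `biofilm_id`,
#'   `condition`, `radius_um`, `angle_px`, `width_um`, `prominence`.
#' @export
widths_to_um <- function(detections, polar, biofilm_id = "biofilm",
                         condition = "unlabelled") {
  stopifnot(inherits(polar, "polar_image"))
  width_um <- arc_length_um(detections$fwhm_px, detections$radius_um,
                            polar$n_angular)
  data.frame(biofilm_id = biofilm_id, condition = condition,
             radius_um = detections$radius_um,
             angle_px = detections$angle_px,
             width_um = width_um,
             prominence = detections$prominence)
}

#' Modified z-scores based on the median absolute deviation
#'
#' `M_i = 0.6745 (x_i - median) / MAD` with `MAD = median(|x_i - median|)`.
#' When the MAD is zero (heavily tied data) the mean absolute deviation is
#' used instead, `M_i = (x_i - median) / (1.253314 meanAD)`; if that is
#' also zero the scores are all zero (no value can be an outlier).
#'
#' @param x Numeric vector (non-empty).
#' @return Numeric vector of modified z-scores.
#' @export
modified_zscore <- function(x) {
  if (!length(x)) stop("empty input", call. = FALSE)
  med <- median(x)
  mad0 <- median(abs(x - med))
  if (mad0 > 0) return(0.6745 * (x - med) / mad0)
  mean_ad <- mean(abs(x - med))
  if (mean_ad > 0) return((x - med) / (1.253314 * mean_ad))
  rep(0, length(x))
}

#' Remove outliers by the modified z-score rule
#'
#' Values whose absolute modified z-score exceeds the threshold (strictly
#' greater) are removed. In the measurement pipeline this is applied once
#' per biofilm across all of its widths, to discard large low-fluorescence
#' regions near the colony edge that the peak detector mistakes for
#' channels.
#'
#' @param x Numeric vector of widths in micrometres (non-empty).
#' @param threshold Modified z-score cutoff (default 3).
#' @return The retained values, in input order.
#' @seealso [outlier_retained()] for the logical mask.
#' @export
remove_outliers <- function(x, threshold = 3) {
  x[outlier_retained(x, threshold)]
}

#' @rdname remove_outliers
#' @return `outlier_retained()` returns a logical vector, `TRUE` for
#'   values that survive the filter.
#' @export
outlier_retained <- function(x, threshold = 3) {
  abs(modified_zscore(x)) <= threshold
}
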