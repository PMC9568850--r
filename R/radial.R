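#' Measure channel widths on a radial grid of circumferences
#'
#' Runs the profile -> peak -> FWHM -> arc-length chain at radii
#' `radius_start_um`, `radius_start_um + radius_step_um`, ... up to the
#' smaller of `max_radius_um` and the polar raster extent. Radii whose
#' circumference is incomplete (invalid samples) are skipped; detections
#' whose half-maximum level is never crossed are discarded (counted in the
#' `"n_discarded"` attribute).
#'
#' @param polar A `polar_image`, already enhanced and inverted so channels
#'   are bright peaks.
#' @param max_radius_um Outer measurement limit in micrometres, normally
#'   the colony's [max_full_circumference_radius()].
#' @param radius_start_um First sampled radius (default 200; below this the
#'   polar unwrap is too distorted for reliable profiles).
#' @param radius_step_um Radial sampling interval (default 50).
#' @param prominence_fraction,min_distance_px Passed to [detect_peaks()].
#' @param biofilm_id,condition Labels stored in the output table.
#' @return A channel width table (see [widths_to_um()]) with an extra
#'   `fwhm_px` column; attribute `"radii_um"` lists the sampled radii and
#'   `"n_discarded"` the number of boundary-failure detections dropped.
#' @export
measure_radial_series <- function(polar, max_radius_um,
                                  radius_start_um = 200,
                                  radius_step_um = 50,
                                  prominence_fraction = 0.20,
                                  min_distance_px = 9L,
                                  biofilm_id = "biofilm",
                                  condition = "unlabelled") {
  stopifnot(inherits(polar, "polar_image"))
  px_um <- polar$calibration$pixel_size_um
  r_cap <- min(max_radius_um, (nrow(polar$pixels) - 1) * px_um)
  if (r_cap < radius_start_um) {
    stop("colony below measurable size (largest full circumference at ",
         round(r_cap), " um < ", radius_start_um, " um)", call. = FALSE)
  }
  radii <- seq(radius_start_um, r_cap, by = radius_step_um)
  rows <- list()
  n_discarded <- 0L
  sampled <- numeric(0)
  for (r in radii) {
    prof <- tryCatch(extract_profile(polar, r), error = function(e) NULL)
    if (is.null(prof)) next
    sampled <- c(sampled, r)
    peaks <- detect_peaks(prof, prominence_fraction, min_distance_px)
    if (!length(peaks)) next
    fwhm <- suppressWarnings(
      vapply(peaks, function(p) peak_fwhm(prof, p), 0))
    ok <- !is.na(fwhm)
    n_discarded <- n_discarded + sum(!ok)
    if (!any(ok)) next
    rows[[length(rows) + 1]] <- data.frame(
      radius_um = prof$radius_um,
      angle_px = as.numeric(peaks[ok]),
      fwhm_px = fwhm[ok],
      prominence = attr(peaks, "prominence")[ok])
  }
  det <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(radius_um = numeric(0), angle_px = numeric(0),
               fwhm_px = numeric(0), prominence = numeric(0))
  }
  out <- widths_to_um(det, polar, biofilm_id, condition)
  out$fwhm_px <- det$fwhm_px
  structure(out, radii_um = sampled, n_discarded = n_discarded)
}

#' Mean channel width per sampled radius
#'
#' @param table A channel width table.
#' @return Data frame with columns `radius_um`, `mean_width_um`, `n`,
#'   ordered by radius. This is the series entering the radial trend fits
#'   ("average channel width against radius").
#' @export
radial_means <- function(table) {
  if (!nrow(table)) {
    return(data.frame(radius_um = numeric(0), mean_width_um = numeric(0),
                      n = integer(0)))
  }
  sp <- split(table$width_um, table$radius_um)
  data.frame(radius_um = as.numeric(names(sp)),
             mean_width_um = vapply(sp, mean, 0),
             n = vapply(sp, length, 0L), row.names = NULL)
}

#' Linear fit of mean width against radius
#'
#' Ordinary least squares of `mean_width_um` on `radius_um`;
#' `R^2 = 1 - SSE/SST` (defined as 0 when the response is constant).
#'
#' @param series Data frame with columns `radius_um` and `mean_width_um`
#'   (at least 3 radii), e.g. from [radial_means()].
#' @return List with `slope` (um per um), `intercept` (um), `r_squared`
#'   and `model = "linear"`.
#' @export
fit_linear <- function(series) {
  x <- series$radius_um; y <- series$mean_width_um
  if (length(x) < 3) stop("need at least 3 radii to fit", call. = FALSE)
  fit <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(residuals(fit)^2) / sst
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, model = "linear")
}

#' Exponential fit of mean width against radius
#'
#' Fits `y = a * exp(b * x)` by least squares of `log(y)` on `x`
#' (log-linear), the convention of spreadsheet exponential trendlines.
#' `R^2` is computed in log space by default; set `r_squared_space =
#' "original"` for `R^2` of the back-transformed curve against the raw
#' series.
#'
#' @param series Data frame with columns `radius_um` and `mean_width_um`
#'   (all positive, at least 3 radii).
#' @param r_squared_space `"log"` (default) or `"original"`.
#' @return List with `a` (um), `b` (per um), `r_squared` and
#'   `model = "exponential"`.
#' @export
fit_exponential <- function(series, r_squared_space = c("log", "original")) {
  r_squared_space <- match.arg(r_squared_space)
  x <- series$radius_um; y <- series$mean_width_um
  if (length(x) < 3) stop("need at least 3 radii to fit", call. = FALSE)
  if (any(y <= 0)) stop("exponential fit requires positive widths",
                        call. = FALSE)
  ly <- log(y)
  fit <- lm(ly ~ x)
  a <- unname(exp(coef(fit)[1])); b <- unname(coef(fit)[2])
  if (r_squared_space == "log") {
    sst <- sum((ly - mean(ly))^2)
    r2 <- if (sst == 0) 0 else 1 - sum(residuals(fit)^2) / sst
  } else {
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 0 else 1 - sum((y - a * exp(b * x))^2) / sst
  }
  list(a = a, b = b, r_squared = r2, model = "exponential")
}

#' Fit both radial trend models
#'
#' @param series Data frame from [radial_means()].
#' @param ... Passed to [fit_exponential()].
#' @return List with elements `linear`, `exponential` and `preferred` (the
#'   model with the higher R-squared).
#' @export
fit_radial_trends <- function(series, ...) {
  lin <- fit_linear(series)
  ex <- fit_exponential(series, ...)
  list(linear = lin, exponential = ex,
       preferred = if (ex$r_squared > lin$r_squared) "exponential"
                   else "linear")
}

#' Widths at normalised radial positions
#'
#' For each fraction f of the largest sampled radius, selects the sampled
#' radius nearest to f times that maximum (ties resolved towards the
#' smaller radius) and returns the widths measured there. Normalised
#' positions let colonies of different sizes be compared like for like.
#'
#' @param table A channel width table.
#' @param fractions Radial fractions (default 20%, 50%, 100%).
#' @return List with `summary` (data frame: `fraction`, `radius_um`, `n`,
#'   `mean_width_um`) and `widths` (list of width vectors named by
#'   fraction).
#' @export
normalised_position_summary <- function(table,
                                        fractions = c(0.2, 0.5, 1.0)) {
  if (!nrow(table)) stop("empty width table", call. = FALSE)
  radii <- sort(unique(table$radius_um))
  rmax <- max(radii)
  pick <- vapply(fractions, function(f) {
    radii[which.min(abs(radii - f * rmax))]
  }, 0)
  widths <- lapply(pick, function(r) table$width_um[table$radius_um == r])
  names(widths) <- format(fractions)
  list(summary = data.frame(fraction = fractions, radius_um = pick,
                            n = vapply(widths, length, 0L),
                            mean_width_um = vapply(widths, mean, 0),
                            row.names = NULL),
       widths = widths)
}
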