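#' Default pipeline configuration
#'
#' All measurement parameters with their standard values: 7200 angular
#' samples per turn, CLAHE block 60 / slope 3 / 256 bins, peak prominence
#' 20% of the profile range, 9-sample minimum peak distance, radial grid
#' 200 um + 50 um steps, modified z-score cutoff 3. `pixel_size_um` has no
#' default: calibration is always an explicit input.
#'
#' The `clahe` and `despeckle` switches control the contrast-enhancement
#' stages. CLAHE exists to make faint channels in real low-contrast images
#' detectable and is on by default; on high-contrast images it is
#' unnecessary and measurably perturbs peak widths (see the methods
#' vignette), so quantitative validation against synthetic ground truth is
#' run with `clahe = FALSE`.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(pixel_size_um = NULL,
       z_step_um = NA,
       median_prefilter_radius_px = 0L,
       n_angular = 7200L,
       clahe = TRUE,
       despeckle = TRUE,
       clahe_block_size = 60L,
       clahe_max_slope = 3,
       clahe_bins = 256L,
       prominence_fraction = 0.20,
       min_distance_px = 9L,
       radius_start_um = 200,
       radius_step_um = 50,
       zscore_threshold = 3,
       fractions = c(0.2, 0.5, 1.0))
}

#' Read/write a pipeline configuration as YAML
#'
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return `read_config()`: the merged configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(user)] <- user
  cfg
}

#' @rdname read_config
#' @param config Configuration list to write.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Measure intra-colony channel widths in one image
#'
#' Runs the full measurement chain: optional median prefilter, colony
#' segmentation (mean-gray-level threshold), centroid centre, largest
#' full-circumference radius, polar unwrap, CLAHE, despeckle, inversion,
#' circumferential peak/FWHM measurement on the radial grid, modified
#' z-score outlier flagging across the colony's widths, and linear +
#' exponential radial trend fits on the retained per-radius means.
#'
#' @param img An [image2d()], a [zstack()] (projected first), or a TIFF
#'   path (then `config$pixel_size_um` must be set).
#' @param config Parameter list from [default_config()] or
#'   [read_config()].
#' @param biofilm_id,condition Labels carried into all output tables.
#' @return Object of class `"channel_measurement"`: list with `widths`
#'   (channel width table with a logical `retained` column), `series`
#'   (retained mean width per radius), `fits` (linear/exponential, `NULL`
#'   when fewer than 3 radii), `positions` (normalised-position summary),
#'   `base_area_um2`, `centre_px`, `max_radius_um`, `mask`, `params`,
#'   `n_discarded`.
#' @export
measure_channels <- function(img, config = default_config(),
                             biofilm_id = "biofilm",
                             condition = "unlabelled") {
  if (is.character(img)) {
    if (is.null(config$pixel_size_um)) {
      stop("config$pixel_size_um must be set to read an image from file ",
           "(calibration is never guessed from metadata)", call. = FALSE)
    }
    img <- read_image(img, calibration(config$pixel_size_um,
                                       config$z_step_um))
  }
  if (inherits(img, "zstack")) img <- max_intensity_projection(img)
  if (!inherits(img, "image2d")) stop("expected an image2d", call. = FALSE)
  if (config$median_prefilter_radius_px > 0) {
    img <- median_prefilter(img, config$median_prefilter_radius_px)
  }
  mask <- segment_colony(img)
  area <- base_area(mask)
  centre <- estimate_centre(mask)
  max_r_um <- max_full_circumference_radius(mask, centre, config$n_angular)
  px_um <- img$calibration$pixel_size_um
  if (max_r_um < config$radius_start_um) {
    stop("colony below measurable size (largest full circumference at ",
         round(max_r_um), " um < ", config$radius_start_um, " um)",
         call. = FALSE)
  }
  polar <- to_polar(img, centre, config$n_angular,
                    max_radius_px = ceiling(max_r_um / px_um) + 2)
  if (isTRUE(config$clahe)) {
    polar <- enhance_clahe(polar, config$clahe_block_size,
                           config$clahe_max_slope, config$clahe_bins)
  }
  if (isTRUE(config$despeckle)) polar <- despeckle(polar)
  polar <- invert_image(polar)
  widths <- measure_radial_series(
    polar, max_r_um, config$radius_start_um, config$radius_step_um,
    config$prominence_fraction, config$min_distance_px,
    biofilm_id, condition)
  n_discarded <- attr(widths, "n_discarded")
  radii_um <- attr(widths, "radii_um")
  widths <- as.data.frame(widths)
  widths$retained <- if (nrow(widths)) {
    outlier_retained(widths$width_um, config$zscore_threshold)
  } else logical(0)
  retained <- widths[widths$retained, , drop = FALSE]
  series <- radial_means(retained)
  fits <- if (nrow(series) >= 3 && all(series$mean_width_um > 0)) {
    fit_radial_trends(series)
  } else NULL
  positions <- if (nrow(retained)) {
    normalised_position_summary(retained, config$fractions)
  } else NULL
  structure(list(widths = widths, series = series, fits = fits,
                 positions = positions, base_area_um2 = area,
                 centre_px = centre, max_radius_um = max_r_um,
                 radii_um = radii_um,
                 mask = mask, params = config,
                 biofilm_id = biofilm_id, condition = condition,
                 n_discarded = n_discarded,
                 package_version = as.character(packageVersion(
                   "colonychannels"))),
            class = "channel_measurement")
}

#' @export
print.channel_measurement <- function(x, ...) {
  cat(sprintf("channel_measurement '%s' (%s)\n", x$biofilm_id,
              x$condition))
  cat(sprintf("  base area: %.0f um^2, centre (%.1f, %.1f) px, ",
              x$base_area_um2, x$centre_px[["x_px"]],
              x$centre_px[["y_px"]]))
  cat(sprintf("max full radius: %.0f um\n", x$max_radius_um))
  cat(sprintf("  %d detections (%d retained) over %d radii; %d discarded ",
              nrow(x$widths), sum(x$widths$retained), nrow(x$series),
              x$n_discarded))
  cat("at profile boundaries\n")
  if (!is.null(x$fits)) {
    cat(sprintf("  linear R^2 = %.3f; exponential R^2 = %.3f (%s trend)\n",
                x$fits$linear$r_squared, x$fits$exponential$r_squared,
                x$fits$preferred))
  }
  invisible(x)
}

#' Write measurement results as CSV plus a run log
#'
#' Writes `widths.csv` (per-detection table with the `retained` flag),
#' `series.csv` (mean width per radius), `fits.csv`, `positions.csv` and
#' `run_log.txt` capturing the package version and every parameter, so a
#' run can be reproduced exactly.
#'
#' @param x A `channel_measurement`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_measurement <- function(x, dir) {
  stopifnot(inherits(x, "channel_measurement"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$widths, file.path(dir, "widths.csv"), row.names = FALSE)
  write.csv(x$series, file.path(dir, "series.csv"), row.names = FALSE)
  if (!is.null(x$fits)) {
    fits <- data.frame(
      biofilm_id = x$biofilm_id, condition = x$condition,
      model = c("linear", "exponential"),
      param1 = c(x$fits$linear$slope, x$fits$exponential$a),
      param2 = c(x$fits$linear$intercept, x$fits$exponential$b),
      r_squared = c(x$fits$linear$r_squared,
                    x$fits$exponential$r_squared))
    write.csv(fits, file.path(dir, "fits.csv"), row.names = FALSE)
  }
  if (!is.null(x$positions)) {
    write.csv(x$positions$summary, file.path(dir, "positions.csv"),
              row.names = FALSE)
  }
  log <- c(sprintf("colonychannels %s", x$package_version),
           sprintf("biofilm_id: %s", x$biofilm_id),
           sprintf("condition: %s", x$condition),
           sprintf("base_area_um2: %.2f", x$base_area_um2),
           sprintf("max_radius_um: %.2f", x$max_radius_um),
           sprintf("n_detections: %d", nrow(x$widths)),
           sprintf("n_retained: %d", sum(x$widths$retained)),
           sprintf("n_discarded_boundary: %d", x$n_discarded),
           "parameters:",
           vapply(names(x$params), function(k) {
             sprintf("  %s: %s", k,
                     paste(format(x$params[[k]]), collapse = ", "))
           }, ""))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
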