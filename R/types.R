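#' Spatial calibration of an image
#'
#' Physical pixel size is a mandatory, explicit input throughout the
#' package: it is never guessed from file metadata, because acquisition
#' metadata for mesoscale systems is frequently absent or inconsistent.
#'
#' @param pixel_size_um Lateral pixel size in micrometres per pixel
#'   (positive).
#' @param z_step_um Axial spacing between z-slices in micrometres
#'   (positive), or `NA` for single-plane images.
#' @return An object of class `"calibration"`.
#' @examples
#' calibration(0.5)
#' calibration(0.5, z_step_um = 3)
#' @export
calibration <- function(pixel_size_um, z_step_um = NA_real_) {
  pixel_size_um <- as.numeric(pixel_size_um)
  z_step_um <- as.numeric(z_step_um)
  if (length(pixel_size_um) != 1 || !is.finite(pixel_size_um) ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number", call. = FALSE)
  }
  if (length(z_step_um) != 1 ||
      (!is.na(z_step_um) && (!is.finite(z_step_um) || z_step_um <= 0))) {
    stop("z_step_um must be a single positive number or NA", call. = FALSE)
  }
  structure(list(pixel_size_um = pixel_size_um, z_step_um = z_step_um),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("calibration:", x$pixel_size_um, "um/px lateral")
  if (!is.na(x$z_step_um)) cat(",", x$z_step_um, "um z-step")
  cat("\n")
  invisible(x)
}

#' Calibrated single-plane grayscale image
#'
#' @param pixels Numeric matrix of non-negative intensities, at least
#'   16 x 16 (rows = y, columns = x, as returned by [tiff::readTIFF()]).
#' @param calibration A [calibration()] object.
#' @param bit_depth Integer bit depth of the intensity range (8 or 16).
#' @return An object of class `"image2d"`.
#' @export
image2d <- function(pixels, calibration, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix (grayscale required)",
         call. = FALSE)
  }
  if (nrow(pixels) < 16 || ncol(pixels) < 16) {
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and non-negative", call. = FALSE)
  }
  if (!inherits(calibration, "calibration")) {
    stop("calibration must be created with calibration()", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16",
                                       call. = FALSE)
  structure(list(pixels = pixels, calibration = calibration,
                 bit_depth = bit_depth),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d px, %d-bit, %g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$calibration$pixel_size_um))
  invisible(x)
}

#' Calibrated confocal z-stack
#'
#' @param slices List of numeric matrices with identical dimensions, in
#'   acquisition (z) order; at least two.
#' @param calibration A [calibration()] object with `z_step_um` set when
#'   axial measurements (thickness) are intended.
#' @param bit_depth Integer bit depth (8 or 16).
#' @return An object of class `"zstack"`.
#' @export
zstack <- function(slices, calibration, bit_depth = 16L) {
  if (!is.list(slices) || length(slices) < 2) {
    stop("a z-stack needs at least 2 slices", call. = FALSE)
  }
  dims <- vapply(slices, function(s) dim(s), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all slices must share the same raster dimensions", call. = FALSE)
  }
  if (!inherits(calibration, "calibration")) {
    stop("calibration must be created with calibration()", call. = FALSE)
  }
  structure(list(slices = slices, calibration = calibration,
                 bit_depth = as.integer(bit_depth)),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("zstack: %d slices of %d x %d px, %d-bit\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$bit_depth))
  invisible(x)
}

# Full-scale intensity for a given bit depth (255 or 65535).
bit_range_max <- function(bit_depth) 2^bit_depth - 1
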