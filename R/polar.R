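#' Unwrap a colony image into polar (radius x angle) coordinates
#'
#' Resamples the image about a centre so that circles of constant radius
#' become rows of the output. Row `i` holds the circle of radius `i - 1`
#' source pixels; the angular axis has exactly `n_angular` samples spanning
#' \[0, 360) degrees, with angle 0 along the +x (column) axis and angle
#' increasing with row index (counter-clockwise in the raster's own
#' coordinate frame). Sampling is bilinear; samples falling outside the
#' frame are marked invalid (`NA`), not zero-filled, so the
#' full-circumference exclusion can be enforced at measurement time.
#'
#' @param img An [image2d()].
#' @param centre Named numeric `c(x_px, y_px)` inside the image.
#' @param n_angular Number of angular samples per full turn (default 7200,
#'   i.e. 20 samples per degree).
#' @param max_radius_px Largest radius (in source pixels) to sample;
#'   defaults to the distance from the centre to the nearest image corner.
#' @return An object of class `"polar_image"`: list with `pixels`
#'   (radius x angle matrix, `NA` = invalid), `centre`, `calibration`,
#'   `n_angular`, `bit_depth`.
#' @export
to_polar <- function(img, centre, n_angular = 7200L, max_radius_px = NULL) {
  if (!inherits(img, "image2d")) stop("expected an image2d", call. = FALSE)
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  cx <- centre[["x_px"]]; cy <- centre[["y_px"]]
  if (cx < 1 || cx > nc || cy < 1 || cy > nr) {
    stop("centre is outside the image frame", call. = FALSE)
  }
  n_angular <- as.integer(n_angular)
  corners <- sqrt(c((cx - 1)^2 + (cy - 1)^2, (nc - cx)^2 + (cy - 1)^2,
                    (cx - 1)^2 + (nr - cy)^2, (nc - cx)^2 + (nr - cy)^2))
  if (is.null(max_radius_px)) max_radius_px <- floor(min(corners))
  max_radius_px <- min(as.integer(max_radius_px), floor(min(corners)))
  theta <- 2 * pi * (seq_len(n_angular) - 1) / n_angular
  r <- 0:max_radius_px
  X <- cx + outer(r, cos(theta))
  Y <- cy + outer(r, sin(theta))
  out <- bilinear_sample(px, X, Y)
  structure(list(pixels = out, centre = c(x_px = cx, y_px = cy),
                 calibration = img$calibration, n_angular = n_angular,
                 bit_depth = img$bit_depth),
            class = "polar_image")
}

# Bilinear interpolation at (X, Y) in 1-based (column, row) coordinates.
# Points with any of the four neighbouring pixels outside the frame give NA.
bilinear_sample <- function(px, X, Y) {
  nr <- nrow(px); nc <- ncol(px)
  x0 <- floor(X); y0 <- floor(Y)
  fx <- X - x0; fy <- Y - y0
  # points exactly on the far edge stay valid
  on_edge_x <- x0 == nc & fx == 0
  on_edge_y <- y0 == nr & fy == 0
  x0[on_edge_x] <- nc - 1; fx[on_edge_x] <- 1
  y0[on_edge_y] <- nr - 1; fy[on_edge_y] <- 1
  valid <- x0 >= 1 & x0 + 1 <= nc & y0 >= 1 & y0 + 1 <= nr
  out <- matrix(NA_real_, nrow(X), ncol(X))
  if (any(valid)) {
    i0 <- y0[valid]; j0 <- x0[valid]
    wx <- fx[valid]; wy <- fy[valid]
    v00 <- px[cbind(i0, j0)]
    v01 <- px[cbind(i0, j0 + 1)]
    v10 <- px[cbind(i0 + 1, j0)]
    v11 <- px[cbind(i0 + 1, j0 + 1)]
    out[valid] <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
      wy * ((1 - wx) * v10 + wx * v11)
  }
  out
}

#' @export
print.polar_image <- function(x, ...) {
  cat(sprintf(
    "polar_image: %d radii x %d angles, centre (%.1f, %.1f), %g um/px\n",
    nrow(x$pixels), x$n_angular, x$centre[["x_px"]], x$centre[["y_px"]],
    x$calibration$pixel_size_um))
  invisible(x)
}

#' Re-project a polar image back to cartesian coordinates
#'
#' Inverse of [to_polar()], used for visual QC and for checking the
#' round-trip fidelity of the unwrap. Each cartesian pixel is bilinearly
#' sampled from the (radius, angle) raster.
#'
#' @param polar A `polar_image`.
#' @param width,height Output raster size in pixels.
#' @return An [image2d()].
#' @export
from_polar <- function(polar, width, height) {
  stopifnot(inherits(polar, "polar_image"))
  cx <- polar$centre[["x_px"]]; cy <- polar$centre[["y_px"]]
  g <- expand.grid(y = seq_len(height), x = seq_len(width))
  dx <- g$x - cx; dy <- g$y - cy
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  # position on the polar raster (1-based): radius r -> row r + 1
  R <- matrix(r + 1, height, width)
  A <- matrix(th / (2 * pi) * polar$n_angular + 1, height, width)
  # wrap the angular axis by padding the first column after the last
  ppx <- cbind(polar$pixels, polar$pixels[, 1])
  out <- bilinear_sample(ppx, A, R)
  out[is.na(out)] <- 0
  image2d(matrix(out, height, width), polar$calibration, polar$bit_depth)
}

#' Convert an angular extent to arc length in micrometres
#'
#' An extent of `delta_angular_px` samples on the angular axis at radius
#' `radius_um` spans the arc `delta_angular_px / n_angular * 2 * pi *
#' radius_um`. This is the polar-geometry conversion that turns an angular
#' full-width at half-maximum into a physical channel width.
#'
#' @param delta_angular_px Angular extent in polar samples (>= 0).
#' @param radius_um Radius in micrometres (>= 0).
#' @param n_angular Angular samples per full turn.
#' @return Arc length in micrometres.
#' @examples
#' arc_length_um(20, 200)  # ~3.491 um
#' @export
arc_length_um <- function(delta_angular_px, radius_um, n_angular = 7200L) {
  if (any(delta_angular_px < 0) || any(radius_um < 0)) {
    stop("delta_angular_px and radius_um must be non-negative",
         call. = FALSE)
  }
  if (any(delta_angular_px > n_angular)) {
    stop("delta_angular_px cannot exceed a full turn", call. = FALSE)
  }
  delta_angular_px / n_angular * 2 * pi * radius_um
}
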