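#' Segment the colony by mean-gray-level threshold
#'
#' The threshold is the arithmetic mean of all pixel gray levels; pixels at
#' or above it are foreground. The largest 8-connected foreground component
#' is retained and interior holes (intra-colony channels, sectors of low
#' fluorescence) are filled, giving a single solid colony footprint.
#'
#' @param img An [image2d()].
#' @return An object of class `"colony_mask"`: list with logical `mask`
#'   (same shape as the image) and the image's `calibration`.
#' @export
segment_colony <- function(img) {
  if (!inherits(img, "image2d")) stop("expected an image2d", call. = FALSE)
  px <- img$pixels
  if (var(as.vector(px)) == 0) {
    stop("no colony detected: image has zero intensity variance",
         call. = FALSE)
  }
  thr <- mean(px)
  fg <- px >= thr
  if (!any(fg)) stop("no colony detected: empty foreground", call. = FALSE)
  lab <- label_components_cpp(fg, 8L)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- fill_holes(mask)
  structure(list(mask = mask, calibration = img$calibration),
            class = "colony_mask")
}

# Fill interior holes: background components (4-connected) not touching the
# frame border become foreground.
fill_holes <- function(mask) {
  bg <- label_components_cpp(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  mask | !(bg %in% c(0L, border))
}

#' @export
print.colony_mask <- function(x, ...) {
  cat(sprintf("colony_mask: %d x %d px, %d foreground px (%.0f um^2)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), base_area(x)))
  invisible(x)
}

#' Colony base area
#'
#' Foreground pixel count times the squared pixel size.
#'
#' @param mask A `colony_mask` from [segment_colony()].
#' @return Base area in square micrometres.
#' @export
base_area <- function(mask) {
  if (!inherits(mask, "colony_mask")) stop("expected a colony_mask",
                                           call. = FALSE)
  sum(mask$mask) * mask$calibration$pixel_size_um^2
}

#' Colony centre from mask centroid
#'
#' The centre of the colony is the centroid (first image moments) of the
#' mask, at sub-pixel precision. This equals the centre that FIJI's
#' "Measure" reports for an oval selection of the whole colony.
#'
#' @param mask A `colony_mask`.
#' @return Named numeric `c(x_px, y_px)` in 1-based pixel coordinates
#'   (x = column, y = row).
#' @export
estimate_centre <- function(mask) {
  if (!inherits(mask, "colony_mask")) stop("expected a colony_mask",
                                           call. = FALSE)
  idx <- which(mask$mask, arr.ind = TRUE)
  c(x_px = mean(idx[, 2]), y_px = mean(idx[, 1]))
}

#' Largest radius with a full circumference inside the colony
#'
#' Returns the largest radius r such that every point of the circle of
#' radius r about the centre lies in the mask foreground, checked at the
#' angular sampling density of the polar transform. Radii beyond this are
#' excluded from width measurement because a full circumferential profile
#' cannot be obtained.
#'
#' @param mask A `colony_mask`.
#' @param centre Named numeric `c(x_px, y_px)` (see [estimate_centre()]).
#' @param n_angular Number of angular samples used for the check.
#' @return Radius in micrometres (0 if no full circle fits).
#' @export
max_full_circumference_radius <- function(mask, centre, n_angular = 7200L) {
  if (!inherits(mask, "colony_mask")) stop("expected a colony_mask",
                                           call. = FALSE)
  m <- mask$mask
  cx <- centre[["x_px"]]; cy <- centre[["y_px"]]
  ci <- round(cy); cj <- round(cx)
  if (ci < 1 || ci > nrow(m) || cj < 1 || cj > ncol(m) || !m[ci, cj]) {
    stop("centre is outside the colony mask", call. = FALSE)
  }
  rmax <- floor(min(cx - 1, ncol(m) - cx, cy - 1, nrow(m) - cy))
  if (rmax < 1) return(0)
  th <- 2 * pi * (seq_len(n_angular) - 1) / n_angular
  radii <- seq_len(rmax)
  full <- logical(rmax)
  for (r in radii) {
    jj <- round(cx + r * cos(th))
    ii <- round(cy + r * sin(th))
    ok <- ii >= 1 & ii <= nrow(m) & jj >= 1 & jj <= ncol(m)
    full[r] <- all(ok) && all(m[cbind(ii, jj)])
  }
  if (!any(full)) return(0)
  max(which(full)) * mask$calibration$pixel_size_um
}

#' Biofilm thickness from the z-axis intensity profile
#'
#' Builds the mean-intensity profile along z (over a region mask or the
#' whole frame), optionally smooths it with a 3-point moving average, and
#' takes the distance between its two lowest local minima (profile ends
#' count as one-sided minima). The two intensity minima bracket the
#' colony's axial extent.
#'
#' @param stack A [zstack()] with `z_step_um` set in its calibration.
#' @param region Optional logical matrix restricting the profile.
#' @param smooth Smooth the profile with a 3-point moving average before
#'   locating minima (default `TRUE`; partial windows at the ends).
#' @return Thickness in micrometres.
#' @export
biofilm_thickness <- function(stack, region = NULL, smooth = TRUE) {
  if (!inherits(stack, "zstack")) stop("expected a zstack", call. = FALSE)
  if (length(stack$slices) < 3) stop("need at least 3 slices",
                                     call. = FALSE)
  zs <- stack$calibration$z_step_um
  if (is.na(zs)) stop("z_step_um is not set in the calibration",
                      call. = FALSE)
  prof <- vapply(stack$slices, function(s) {
    if (is.null(region)) mean(s) else mean(s[region])
  }, 0)
  p <- if (smooth) moving_average3(prof) else prof
  mins <- local_minima(p)
  if (length(mins) < 2) stop("thickness undefined: fewer than two local ",
                             "minima on the z profile", call. = FALSE)
  two <- sort(mins[order(p[mins])][1:2])
  (two[2] - two[1]) * zs
}

moving_average3 <- function(p) {
  n <- length(p)
  out <- (c(p[1], p[-n]) + p + c(p[-1], p[n])) / 3
  out[1] <- mean(p[1:2])
  out[n] <- mean(p[(n - 1):n])
  out
}

# Indices of local minima; equal-value plateaus are collapsed to their
# first index and profile ends are compared one-sided.
local_minima <- function(p) {
  n <- length(p)
  left <- c(Inf, p[-n])
  right <- c(p[-1], Inf)
  cand <- which(p <= left & p <= right)
  if (length(cand) < 2) return(cand)
  same_run <- c(FALSE, diff(cand) == 1 &
                  p[cand[-1]] == p[cand[-length(cand)]])
  cand[!same_run]
}
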