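#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Equalises contrast in contextual tiles of about `block_size` pixels,
#' clipping each tile histogram so the transfer-function slope never
#' exceeds `max_slope`, with bilinear blending between tiles (Zuiderveld's
#' algorithm, as in FIJI's CLAHE with the same parameters). The output
#' occupies the image's bit range.
#'
#' Invalid (out-of-frame) polar samples are filled by replicating the last
#' valid value along the radial axis before equalisation and re-masked
#' afterwards, so the frame edge cannot distort histograms near the colony
#' rim.
#'
#' @param img A `polar_image` (or [image2d()]).
#' @param block_size Contextual tile size in pixels (default 60).
#' @param max_slope Histogram clip limit expressed as the maximum slope of
#'   the cumulative transfer function (default 3).
#' @param bins Number of histogram bins (default 256).
#' @return Object of the same class with equalised intensities.
#' @export
enhance_clahe <- function(img, block_size = 60L, max_slope = 3,
                          bins = 256L) {
  apply_px(img, function(px, bit_depth) {
    if (block_size > nrow(px) || block_size > ncol(px)) {
      stop("block_size is larger than the image", call. = FALSE)
    }
    maxv <- bit_range_max(bit_depth)
    nx <- max(2L, as.integer(round(nrow(px) / block_size)))
    ny <- max(2L, as.integer(round(ncol(px) / block_size)))
    pr <- ceiling(nrow(px) / nx) * nx - nrow(px)
    pc <- ceiling(ncol(px) / ny) * ny - ncol(px)
    padded <- px
    if (pr > 0) padded <- rbind(padded,
                                padded[rep(nrow(padded), pr), , drop = FALSE])
    if (pc > 0) padded <- cbind(padded, padded[, seq_len(pc), drop = FALSE])
    eq <- EBImage::clahe(padded / maxv, nx = nx, ny = ny, bins = bins,
                         limit = max_slope)
    eq <- matrix(as.numeric(eq), nrow(padded), ncol(padded))
    round(pmin(pmax(eq[seq_len(nrow(px)), seq_len(ncol(px))], 0), 1) * maxv)
  })
}

#' Despeckle (3 x 3 median filter)
#'
#' The FIJI "Despeckle" operation: each pixel is replaced by the median of
#' its 3 x 3 neighbourhood (edge-replicated borders). Removes single-pixel
#' noise without widening the value range.
#'
#' @param img A `polar_image` (or [image2d()]).
#' @return Object of the same class, despeckled.
#' @export
despeckle <- function(img) {
  off <- box_offsets(1L)
  apply_px(img, function(px, bit_depth) median_filter_cpp(px, off$dy, off$dx))
}

#' Invert image intensities
#'
#' Bit-range complement `I' = (2^bit - 1) - I`. After inversion the dark
#' intra-colony channels appear as bright peaks on circumferential
#' profiles, which is what the peak detector expects.
#'
#' @param img A `polar_image` (or [image2d()]).
#' @return Object of the same class, inverted.
#' @export
invert_image <- function(img) {
  apply_px(img, function(px, bit_depth) bit_range_max(bit_depth) - px)
}

# Apply a raster transform to an image2d or polar_image, preserving the
# invalid-sample (NA) flags of polar images: NAs are filled by replicating
# the last valid value along the radial axis, the transform runs on the
# filled raster, and the flags are restored.
apply_px <- function(img, fun) {
  if (inherits(img, "polar_image")) {
    na_mask <- is.na(img$pixels)
    filled <- if (any(na_mask)) locf_down(img$pixels) else img$pixels
    out <- fun(filled, img$bit_depth)
    out[na_mask] <- NA_real_
    img$pixels <- out
    img
  } else if (inherits(img, "image2d")) {
    img$pixels <- fun(img$pixels, img$bit_depth)
    img
  } else {
    stop("expected a polar_image or image2d", call. = FALSE)
  }
}

# Last-observation-carried-forward down each column. Row 1 of a polar
# raster (the centre) is always valid, so the carry never has to cross a
# column boundary.
locf_down <- function(m) {
  v <- as.vector(m)
  ok <- !is.na(v)
  src <- cummax(ifelse(ok, seq_along(v), 0L))
  matrix(v[src], nrow(m), ncol(m))
}
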