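#' Read a calibrated TIFF image or z-stack
#'
#' Reads an 8- or 16-bit grayscale TIFF. A single-page file becomes an
#' [image2d()]; a multi-page file becomes a [zstack()] with pages in file
#' order. Intensities are preserved bit-exactly.
#'
#' @param path Path to a TIFF file.
#' @param calibration A [calibration()] object; there is no default pixel
#'   size and none is read from file metadata.
#' @return An `image2d` (one page) or `zstack` (several pages).
#' @export
read_image <- function(path, calibration) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!inherits(calibration, "calibration")) {
    stop("calibration must be created with calibration()", call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE),
                    error = function(e) {
                      stop("unreadable TIFF: ", conditionMessage(e),
                           call. = FALSE)
                    })
  check_page <- function(p) {
    if (length(dim(p)) == 3) stop("grayscale required (RGB/multichannel ",
                                  "TIFF not supported)", call. = FALSE)
    storage.mode(p) <- "double"
    p
  }
  pages <- lapply(pages, check_page)
  bit_depth <- if (max(vapply(pages, max, 0)) > 255) 16L else 8L
  if (length(pages) == 1) {
    image2d(pages[[1]], calibration, bit_depth)
  } else {
    zstack(pages, calibration, bit_depth)
  }
}

#' Write an image, z-stack or mask to TIFF
#'
#' Intensities are stored at the object's bit depth; the round trip through
#' [read_image()] is bit-exact. Colony masks are written as 8-bit 0/255.
#'
#' @param x An `image2d`, `zstack` or `colony_mask`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "colony_mask")) {
    tiff::writeTIFF(ifelse(x$mask, 1, 0), path, bits.per.sample = 8L)
    return(invisible(path))
  }
  maxv <- bit_range_max(x$bit_depth)
  if (inherits(x, "image2d")) {
    tiff::writeTIFF(x$pixels / maxv, path, bits.per.sample = x$bit_depth)
  } else if (inherits(x, "zstack")) {
    tiff::writeTIFF(lapply(x$slices, function(s) s / maxv), path,
                    bits.per.sample = x$bit_depth)
  } else {
    stop("cannot write object of class ", class(x)[1], call. = FALSE)
  }
  invisible(path)
}

#' Maximum intensity projection of a z-stack
#'
#' Each output pixel is the maximum over all slices at that position, the
#' standard way to display a confocal stack of a dome-shaped colony as a
#' single plane.
#'
#' @param stack A [zstack()].
#' @return An [image2d()] with the stack's calibration.
#' @export
max_intensity_projection <- function(stack) {
  if (!inherits(stack, "zstack")) stop("expected a zstack", call. = FALSE)
  proj <- Reduce(pmax, stack$slices)
  image2d(proj, stack$calibration, stack$bit_depth)
}

#' Median prefilter with a disk neighbourhood
#'
#' Rank-median filter over a disk-shaped structuring element (all offsets
#' with `dx^2 + dy^2 <= radius_px^2`), the shape used by FIJI's
#' "Median..." command. Borders are edge-replicated so the colony rim is
#' not darkened by the background.
#'
#' @param img An [image2d()].
#' @param radius_px Disk radius in pixels (>= 1).
#' @return The filtered `image2d`, same dimensions.
#' @export
median_prefilter <- function(img, radius_px = 2L) {
  if (!inherits(img, "image2d")) stop("expected an image2d", call. = FALSE)
  radius_px <- as.integer(radius_px)
  if (radius_px < 1) stop("radius_px must be >= 1", call. = FALSE)
  off <- disk_offsets(radius_px)
  out <- median_filter_cpp(img$pixels, off$dy, off$dx)
  image2d(out, img$calibration, img$bit_depth)
}

# Offsets of a disk-shaped structuring element of the given pixel radius.
disk_offsets <- function(radius_px) {
  g <- expand.grid(dy = -radius_px:radius_px, dx = -radius_px:radius_px)
  keep <- g$dy^2 + g$dx^2 <= radius_px^2
  list(dy = as.integer(g$dy[keep]), dx = as.integer(g$dx[keep]))
}

# Offsets of a square box element of side 2*radius+1 (FIJI Despeckle = 3x3).
box_offsets <- function(radius_px) {
  g <- expand.grid(dy = -radius_px:radius_px, dx = -radius_px:radius_px)
  list(dy = as.integer(g$dy), dx = as.integer(g$dx))
}
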