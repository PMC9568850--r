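# Fixture builders (all generated in code; nothing on disk).

cal1 <- function(px = 1, z = NA) calibration(px, z)

# Filled disk (value `fg` on `bg`) in a size x size frame.
disk_image <- function(size = 64, R = 15, cx = (size + 1) / 2,
                       cy = (size + 1) / 2, fg = 200, bg = 0, px_um = 1,
                       bit_depth = 16L) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  m <- matrix(bg, size, size)
  m[(xs - cx)^2 + (ys - cy)^2 <= R^2] <- fg
  image2d(m, cal1(px_um), bit_depth)
}

# Smooth radial ring: gaussian cross-section around radius r0.
ring_image <- function(size = 256, r0 = 100, sigma = 2, height = 1000,
                       px_um = 1) {
  cx <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  r <- sqrt((xs - cx)^2 + (ys - cx)^2)
  image2d(height * exp(-(r - r0)^2 / (2 * sigma^2)), cal1(px_um), 16L)
}

# Gaussian peak profile (already "inverted": channel as a bright peak).
gauss_profile <- function(n = 720, centre = n / 2, sigma = 3, height = 100,
                          base = 10) {
  i <- seq_len(n)
  base + height * exp(-(i - centre)^2 / (2 * sigma^2))
}

# A small polar image built directly (radii x angles) with gaussian-peak
# channels at fixed angular positions; pixel size 1 um/px.
synth_polar <- function(n_radii = 431, n_angular = 720, peak_sigma_px = 8,
                        peak_angles = c(100, 300, 550), height = 150,
                        base = 20, px_um = 1) {
  m <- matrix(base, n_radii, n_angular)
  i <- seq_len(n_angular)
  for (a in peak_angles) {
    d <- abs(i - a)
    d <- pmin(d, n_angular - d)
    m <- m + matrix(height * exp(-d^2 / (2 * peak_sigma_px^2)), n_radii,
                    n_angular, byrow = TRUE)
  }
  structure(list(pixels = m, centre = c(x_px = 0, y_px = 0),
                 calibration = cal1(px_um), n_angular = n_angular,
                 bit_depth = 16L),
            class = "polar_image")
}

# Cached expensive fixtures, shared across test files.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# A mid-sized rendered colony (R = 500 um, 12 constant-width channels) and
# its measurement with contrast enhancement off.
fx_colony <- function() {
  fixture("colony", function() {
    synth_colony(synthetic_spec(image_size_px = 800, colony_radius_um = 500,
                                n_channels = 12, seed = 7))
  })
}

fx_measurement <- function() {
  fixture("measurement", function() {
    cfg <- default_config()
    cfg$clahe <- FALSE
    measure_channels(fx_colony()$image, cfg, biofilm_id = "fx",
                     condition = "fixture")
  })
}
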