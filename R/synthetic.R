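#' Specification for a synthetic colony biofilm image
#'
#' Describes a roughly elliptical, dome-profiled bright colony on a dark
#' background, carved with darker channel curves radiating from the
#' centre. Channel cross-sections are raised half-cosine valleys, so the
#' programmed local width *is* the full-width at half-maximum by
#' construction and ground truth is unambiguous. The rendered image is
#' degraded by Gaussian blur and noise.
#'
#' Width laws (all in micrometres, radius `r` in micrometres):
#' constant `w0`; linear `w0 + slope * r`; exponential `w0 * exp(rate *
#' r)`. Defaults emulate mature colonies a couple of millimetres across
#' with channels in the 10-20 um range, the scale at which channels are
#' observed in mesoscale fluorescence images.
#'
#' @param image_size_px Square frame side in pixels.
#' @param pixel_size_um Lateral calibration in um/px.
#' @param colony_radius_um Semi-major axis of the colony ellipse (um).
#' @param axis_ratio Minor/major axis ratio in (0, 1].
#' @param centre_offset_px Colony centre offset from the frame centre,
#'   `c(x, y)` in pixels.
#' @param n_channels Number of channels (0 for a plain dome colony).
#' @param width_law `"constant"`, `"linear"` or `"exponential"`.
#' @param w0_um Width-law base width (um).
#' @param slope Linear width-law slope (um per um of radius).
#' @param rate Exponential width-law rate (per um of radius).
#' @param meander_amplitude Angular wander of channel trajectories
#'   (radians RMS); 0 gives straight radial channels (the nutrient-limited
#'   regime), larger values give wandering, sharply turning channels (the
#'   nutrient-rich regime).
#' @param channel_depth Fractional intensity drop at the channel centre
#'   relative to the local colony intensity, in (0, 1).
#' @param dome_exponent Exponent p of the dome profile
#'   `rim + (1 - rim) * (1 - rho^p)` (rho = normalised elliptical radius).
#' @param rim_intensity Colony intensity at the rim as a fraction of the
#'   peak, in (0, 1).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 = none).
#' @param noise_sd Additive Gaussian noise sigma as a fraction of the bit
#'   range (0 = none).
#' @param poisson_noise Replace intensities by Poisson draws (shot noise).
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(image_size_px = 1600L, pixel_size_um = 2,
                           colony_radius_um = 1100, axis_ratio = 1,
                           centre_offset_px = c(0, 0), n_channels = 24L,
                           width_law = c("constant", "linear",
                                         "exponential"),
                           w0_um = 12, slope = 0.008, rate = 6e-4,
                           meander_amplitude = 0, channel_depth = 0.8,
                           dome_exponent = 2, rim_intensity = 0.35,
                           blur_sigma_px = 0.5, noise_sd = 0.01,
                           poisson_noise = FALSE, bit_depth = 16L,
                           seed = 1L) {
  width_law <- match.arg(width_law)
  stopifnot(axis_ratio > 0, axis_ratio <= 1, channel_depth > 0,
            channel_depth < 1, rim_intensity > 0, rim_intensity < 1,
            w0_um > 0, n_channels >= 0)
  spec <- list(image_size_px = as.integer(image_size_px),
               pixel_size_um = pixel_size_um,
               colony_radius_um = colony_radius_um,
               axis_ratio = axis_ratio,
               centre_offset_px = centre_offset_px,
               n_channels = as.integer(n_channels),
               width_law = width_law, w0_um = w0_um, slope = slope,
               rate = rate, meander_amplitude = meander_amplitude,
               channel_depth = channel_depth,
               dome_exponent = dome_exponent,
               rim_intensity = rim_intensity,
               blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
               poisson_noise = poisson_noise,
               bit_depth = as.integer(bit_depth), seed = seed)
  class(spec) <- "synthetic_spec"
  law <- width_law_fun(spec)
  r_grid <- seq(0, colony_radius_um, length.out = 200)
  if (any(law(r_grid) <= 0)) {
    stop("width law must be positive over the whole colony", call. = FALSE)
  }
  # packing limit: channels must not overlap where measurement starts
  if (n_channels > 0) {
    circ200 <- 2 * pi * 200
    if (n_channels * law(200) > 0.7 * circ200) {
      stop("channels would overlap at r = 200 um: reduce n_channels or ",
           "the programmed width (packing limit 70% of the circumference)",
           call. = FALSE)
    }
  }
  half <- (image_size_px - 1) / 2
  if (colony_radius_um / pixel_size_um +
      max(abs(centre_offset_px)) > half - 2) {
    stop("colony does not fit inside the frame; enlarge image_size_px",
         call. = FALSE)
  }
  spec
}

# The programmed width law as a function of radius (um -> um FWHM).
width_law_fun <- function(spec) {
  switch(spec$width_law,
         constant = function(r) rep(spec$w0_um, length(r)),
         linear = function(r) spec$w0_um + spec$slope * r,
         exponential = function(r) spec$w0_um * exp(spec$rate * r))
}

#' Render a synthetic colony image with ground truth
#'
#' Renders the colony described by a [synthetic_spec()]: an elliptical
#' dome-profiled bright body on a dark background, with `n_channels` dark
#' channel curves whose local full-width at half-maximum (perpendicular to
#' the channel axis) follows the programmed width law. Channel
#' trajectories start as evenly spaced radial rays (with a small random
#' angular jitter) and wander by a smoothed random angular walk when
#' `meander_amplitude > 0`; channels fade in between 60 and 140 um (the
#' colony centre stays solid) and fade out at 92-95% of the colony radius
#' (channels are interior structures and the rim stays closed). Blur is
#' applied before noise. The render is deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `image` (an [image2d()]) and `truth` (class
#'   `"synthetic_truth"`: the spec, true centre in pixel coordinates, true
#'   base area in um^2, the width-law function and per-channel angular
#'   trajectory functions).
#' @export
synth_colony <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, synth_colony_impl(spec))
}

synth_colony_impl <- function(spec) {
  size <- spec$image_size_px
  px <- spec$pixel_size_um
  maxv <- bit_range_max(spec$bit_depth)
  peak <- 0.78 * maxv
  bg <- 0.02 * maxv
  cx <- (size + 1) / 2 + spec$centre_offset_px[1]
  cy <- (size + 1) / 2 + spec$centre_offset_px[2]
  Rx <- spec$colony_radius_um
  Ry <- Rx * spec$axis_ratio
  xs <- (seq_len(size) - cx) * px
  ys <- (seq_len(size) - cy) * px
  Xm <- matrix(xs, size, size, byrow = TRUE)
  Ym <- matrix(ys, size, size)
  rho <- sqrt((Xm / Rx)^2 + (Ym / Ry)^2)
  inside <- rho <= 1
  dome <- spec$rim_intensity +
    (1 - spec$rim_intensity) * (1 - pmin(rho, 1)^spec$dome_exponent)
  colony <- peak * dome * inside
  law <- width_law_fun(spec)
  channels <- list()
  if (spec$n_channels > 0) {
    r_um <- sqrt(Xm^2 + Ym^2)
    th <- atan2(Ym, Xm)
    spacing <- 2 * pi / spec$n_channels
    theta0 <- (seq_len(spec$n_channels) - 1) * spacing +
      runif(spec$n_channels, -0.15, 0.15) * spacing
    # channels span 60 um .. 95% of the (elliptical) rim with smooth
    # ramps: the colony centre stays solid and the rim stays closed
    # (channels are interior structures; a breached rim would also
    # invalidate the mask-based full-circumference rule)
    fade <- pmin(1, pmax(0, (r_um - 60) / 80)) *
      pmin(1, pmax(0, (0.95 - rho) / 0.03))
    w <- law(r_um)
    for (k in seq_len(spec$n_channels)) {
      traj <- channel_trajectory(theta0[k], spec$meander_amplitude, Rx)
      thc <- traj$theta(r_um)
      dphi <- traj$dtheta_dr(r_um)
      cosphi <- 1 / sqrt(1 + (r_um * dphi)^2)
      dth <- ((th - thc + pi) %% (2 * pi)) - pi
      d_perp <- r_um * dth * cosphi
      hit <- abs(d_perp) <= w
      cross <- ifelse(hit, cos(pi * d_perp / (2 * w))^2, 0)
      colony <- colony * (1 - spec$channel_depth * fade * cross)
      channels[[k]] <- traj
    }
  }
  img <- bg + colony
  if (spec$blur_sigma_px > 0) {
    img <- EBImage::gblur(img / maxv, sigma = spec$blur_sigma_px)
    img <- matrix(as.numeric(img), size, size) * maxv
  }
  if (spec$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, spec$noise_sd * maxv)
  }
  if (spec$poisson_noise) {
    img <- matrix(rpois(length(img), pmax(img, 0)), size, size)
  }
  img <- round(pmin(pmax(img, 0), maxv))
  truth <- structure(
    list(spec = spec, centre_px = c(x_px = cx, y_px = cy),
         base_area_um2 = pi * Rx * Ry, colony_radius_um = Rx,
         axis_ratio = spec$axis_ratio, width_law = law,
         channels = channels, n_channels = spec$n_channels),
    class = "synthetic_truth")
  list(image = image2d(img, calibration(px), spec$bit_depth),
       truth = truth)
}

# Angular trajectory theta(r) of one channel: theta0 plus a smoothed,
# amplitude-scaled random walk over radial knots. Returns the trajectory
# and its radial derivative (for the perpendicular-width tilt correction).
channel_trajectory <- function(theta0, amplitude, max_radius_um) {
  knots <- seq(0, max_radius_um * 1.3, by = 50)
  if (amplitude <= 0 || length(knots) < 5) {
    return(list(theta = function(r) rep(theta0, length(r)),
                dtheta_dr = function(r) rep(0, length(r))))
  }
  walk <- cumsum(rnorm(length(knots)))
  walk <- stats::filter(walk, rep(1 / 5, 5), sides = 2)
  walk[is.na(walk)] <- 0
  walk <- as.numeric(walk)
  s <- sd(walk)
  if (s > 0) walk <- walk / s * amplitude
  th_fun <- stats::splinefun(knots, theta0 + walk, method = "natural")
  list(theta = function(r) th_fun(r),
       dtheta_dr = function(r) th_fun(r, deriv = 1))
}

#' True mean channel width at given radii
#'
#' Evaluates the ground-truth width law of a synthetic colony at each
#' radius of a sampling grid.
#'
#' @param truth A `"synthetic_truth"` object from [synth_colony()].
#' @param radii_um Numeric vector of radii in micrometres.
#' @return Data frame with `radius_um` and `true_width_um`.
#' @export
ground_truth_series <- function(truth, radii_um) {
  stopifnot(inherits(truth, "synthetic_truth"))
  data.frame(radius_um = radii_um,
             true_width_um = truth$width_law(radii_um))
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit(if (had) assign(".Random.seed", old, envir = genv)
          else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv))
  set.seed(seed)
  expr
}
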