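#' Detect peaks on a circular intensity profile
#'
#' Finds local maxima on a circumferential profile, treating the profile as
#' circular (a circumference has no endpoints): wrap-around applies to
#' maxima, prominences and inter-peak distances alike. A maximum is kept if
#' its topographic prominence is at least `prominence_fraction` times the
#' profile's intensity range; among maxima closer than `min_distance_px`
#' angular samples, the higher survives (processed in decreasing height
#' order). Equal-value plateaus count as one maximum at their middle
#' sample.
#'
#' @param profile A `profile` object from [extract_profile()] or a numeric
#'   vector of intensities.
#' @param prominence_fraction Minimum prominence as a fraction of
#'   `max(profile) - min(profile)` (default 0.20).
#' @param min_distance_px Minimum circular distance between retained peaks
#'   in angular samples (default 9).
#' @return Sorted integer vector of peak indices (1-based), with the
#'   matching prominences in attribute `"prominence"`. A flat profile
#'   yields an empty result.
#' @export
detect_peaks <- function(profile, prominence_fraction = 0.20,
                         min_distance_px = 9L) {
  v <- profile_values(profile)
  n <- length(v)
  if (n < 2 * min_distance_px) {
    stop("profile shorter than twice min_distance_px", call. = FALSE)
  }
  if (anyNA(v)) stop("profile contains invalid samples", call. = FALSE)
  rng <- max(v) - min(v)
  empty <- structure(integer(0), prominence = numeric(0))
  if (rng == 0) return(empty)
  cand <- circular_local_maxima(v)
  if (!length(cand)) return(empty)
  proms <- vapply(cand, function(i) circular_prominence(v, i), 0)
  keep <- proms >= prominence_fraction * rng
  cand <- cand[keep]; proms <- proms[keep]
  if (!length(cand)) return(empty)
  # enforce the minimum distance, highest peaks first
  ord <- order(-v[cand], cand)
  alive <- rep(TRUE, length(cand))
  for (o in ord) {
    if (!alive[o]) next
    d <- abs(cand - cand[o])
    d <- pmin(d, n - d)
    alive[d < min_distance_px & seq_along(cand) != o] <- FALSE
  }
  out <- order(cand[alive])
  structure(cand[alive][out], prominence = proms[alive][out])
}

# Local maxima of a circular sequence with plateau collapsing: a run of
# equal values is a maximum if both neighbouring runs are lower; the run's
# middle sample is reported.
circular_local_maxima <- function(v) {
  n <- length(v)
  if (all(v == v[1])) return(integer(0))
  s <- which(v != v[1])[1]
  rot <- if (s > 1) c(v[s:n], v[seq_len(s - 1)]) else v
  r <- rle(rot)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  prevv <- r$values[c(k, seq_len(k - 1))]
  nextv <- r$values[c(seq_len(k - 1) + 1, 1)]
  is_peak <- r$values > prevv & r$values > nextv
  mid <- floor((starts + ends) / 2)
  sort(((mid[is_peak] - 1) + (s - 1)) %% n + 1)
}

# Topographic prominence of v[i] on a circular profile: walk from the peak
# in each direction to the nearest strictly higher sample (or the whole
# circle for a global maximum); the prominence is the peak height minus the
# higher of the two interval minima.
circular_prominence <- function(v, i) {
  n <- length(v)
  higher <- which(v > v[i])
  if (!length(higher)) return(v[i] - min(v))
  dl <- (i - higher) %% n
  dl[dl == 0] <- n
  dr <- (higher - i) %% n
  dr[dr == 0] <- n
  dL <- min(dl); dR <- min(dr)
  left_min <- min(v[((seq(i - dL, i) - 1) %% n) + 1])
  right_min <- min(v[((seq(i, i + dR) - 1) %% n) + 1])
  v[i] - max(left_min, right_min)
}

#' Full-width at half-maximum of a detected peak
#'
#' The half-maximum level is referenced to the peak's prominence (level =
#' peak height minus half the prominence), which matches the standard
#' FWHM-of-a-peak definition and is robust to sloping baselines. Crossing
#' points on each side are located by linear interpolation between
#' samples, with circular indexing. If the level is never crossed on one
#' side (the peak sits at the boundary of valid data), `NA` is returned
#' with a warning and the detection should be discarded.
#'
#' @param profile A `profile` object or numeric vector.
#' @param peak_index Index of a peak returned by [detect_peaks()].
#' @return Width in angular samples (possibly fractional), or `NA`.
#' @export
peak_fwhm <- function(profile, peak_index) {
  v <- profile_values(profile)
  n <- length(v)
  i <- as.integer(peak_index)
  prom <- circular_prominence(v, i)
  if (prom <= 0) {
    warning("peak has zero prominence; FWHM undefined")
    return(NA_real_)
  }
  level <- v[i] - prom / 2
  fwd <- v[((i - 1 + 0:(n - 1)) %% n) + 1]
  bwd <- v[((i - 1 - 0:(n - 1)) %% n) + 1]
  right_off <- half_crossing_offset(fwd, level)
  left_off <- half_crossing_offset(bwd, level)
  if (is.na(right_off) || is.na(left_off)) {
    warning("half-maximum level never crossed on one side; ",
            "detection discarded")
    return(NA_real_)
  }
  left_off + right_off
}

# Offset (in samples, from position 1) at which the sequence first drops
# below `level`, linearly interpolated; NA if it never does.
half_crossing_offset <- function(w, level) {
  below <- which(w < level)
  if (!length(below)) return(NA_real_)
  j <- below[1]
  if (j == 1) return(0)
  (j - 2) + (w[j - 1] - level) / (w[j - 1] - w[j])
}

profile_values <- function(profile) {
  if (inherits(profile, "profile")) profile$values else as.numeric(profile)
}
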