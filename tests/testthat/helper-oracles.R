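# Independent brute-force oracles. These deliberately mirror the stated
# definitions with plain loops, not the package's vectorised/compiled
# implementations.

# Rank-median filter over explicit offsets with edge replication.
oracle_median_filter <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- pmin(pmax(i + dy, 1), nr)
      jj <- pmin(pmax(j + dx, 1), nc)
      out[i, j] <- median(m[cbind(ii, jj)])
    }
  }
  out
}

oracle_disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= r^2, ]
  list(dy = g$dy, dx = g$dx)
}

# Topographic prominence on a circular profile by literal walking.
oracle_prominence <- function(v, i) {
  n <- length(v)
  walk <- function(step) {
    lo <- v[i]
    j <- i
    for (k in seq_len(n - 1)) {
      j <- ((j - 1 + step) %% n) + 1
      if (v[j] > v[i]) return(lo)
      if (v[j] < lo) lo <- v[j]
    }
    min(v)  # no higher sample anywhere: global maximum
  }
  v[i] - max(walk(1), walk(-1))
}

# Circular peak detection by exhaustive scan: plateau-aware local maxima,
# prominence threshold, then greedy distance pruning (higher first).
oracle_detect_peaks <- function(v, frac = 0.20, mindist = 9) {
  n <- length(v)
  if (max(v) == min(v)) return(integer(0))
  cand <- integer(0)
  for (i in seq_len(n)) {
    l <- i
    while (v[((l - 2) %% n) + 1] == v[i]) {
      l <- ((l - 2) %% n) + 1
      if (l == i) break
    }
    r <- i
    while (v[(r %% n) + 1] == v[i]) {
      r <- (r %% n) + 1
      if (r == i) break
    }
    if (v[((l - 2) %% n) + 1] < v[i] && v[(r %% n) + 1] < v[i]) {
      len <- ((r - l) %% n)
      mid <- ((l - 1 + floor(len / 2)) %% n) + 1
      if (i == mid) cand <- c(cand, i)
    }
  }
  proms <- vapply(cand, function(i) oracle_prominence(v, i), 0)
  keep <- proms >= frac * (max(v) - min(v))
  cand <- cand[keep]
  alive <- rep(TRUE, length(cand))
  for (o in order(-v[cand], cand)) {
    if (!alive[o]) next
    d <- abs(cand - cand[o])
    d <- pmin(d, n - d)
    alive[d < mindist & seq_along(cand) != o] <- FALSE
  }
  sort(cand[alive])
}

# Modified z-score outlier rule, straight from its definition.
oracle_retained <- function(x, threshold = 3) {
  med <- median(x)
  mad0 <- median(abs(x - med))
  M <- if (mad0 > 0) {
    0.6745 * (x - med) / mad0
  } else {
    mean_ad <- mean(abs(x - med))
    if (mean_ad > 0) (x - med) / (1.253314 * mean_ad) else rep(0, length(x))
  }
  abs(M) <= threshold
}

# Mann-Whitney U (midranks) plus the exact two-sided p-value by full
# enumeration of all C(na+nb, na) group labelings.
oracle_mw_enumeration <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    rk <- rank(pooled)
    sum(rk[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * nb / 2
  labelings <- utils::combn(na + nb, na)
  us <- apply(labelings, 2, u_of)
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p_value = p)
}

# Zuiderveld single-tile CLAHE mapping: histogram over 256 bins (16-bit
# internal binning), clip at limit * npx / bins with iterative excess
# redistribution, map through the clipped CDF.
oracle_clahe_tile <- function(tile, limit, bins = 256) {
  npx <- length(tile)
  v16 <- round(tile * 65535)
  binsize <- 1 + 65535 %/% bins
  bin <- v16 %/% binsize
  h <- tabulate(bin + 1, nbins = bins)
  clip <- max(limit * npx / bins, 1)
  excess <- sum(pmax(h - clip, 0))
  h2 <- pmin(h, clip)
  repeat {
    h3 <- pmin(h2 + excess / bins, clip)
    new_excess <- excess - sum(h3 - h2)
    h2 <- h3
    if (new_excess <= 1e-9 || new_excess >= excess) break
    excess <- new_excess
  }
  matrix((cumsum(h2) / npx)[bin + 1], nrow(tile), ncol(tile))
}

# Smooth random circular profiles with a few bumps, for peak-detector
# equivalence testing.
random_profile <- function(n = 80) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  k <- sample(2:4, 1)
  v <- rep(10, n)
  for (i in seq_len(k)) {
    v <- v + runif(1, 5, 60) *
      exp(-((((th - runif(1, 0, 2 * pi) + pi) %% (2 * pi)) - pi)^2) /
            (2 * runif(1, 0.05, 0.4)^2))
  }
  v + rnorm(n, 0, 0.5)
}
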