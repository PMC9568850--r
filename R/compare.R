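#' Mann-Whitney U rank test
#'
#' Rank-sum U statistic with midrank tie handling. The two-sided p-value
#' uses the exact null distribution when `n_a * n_b <= 400` and the data
#' contain no ties, and the normal approximation with tie correction and
#' continuity correction otherwise. Chosen over parametric tests because
#' width and area samples are typically non-normal with unequal sizes.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `U` (for sample `a`), `p_value`, `n_a`, `n_b` and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty",
                                     call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA",
                                 call. = FALSE)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && na * nb <= 400) {
    # exact: P(U <= u) + P(U >= u) via the symmetric null distribution
    p <- min(1, 2 * min(pwilcox(U, na, nb),
                        pwilcox(na * nb - U, na, nb)))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    n <- na + nb
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(U = U, p_value = p, n_a = na, n_b = nb, method = method)
}

#' Boxplot-style summary of a group of measurements
#'
#' Quartiles use linear interpolation of the empirical distribution
#' (R/NumPy default, type 7). Whiskers follow the 1.5 x IQR rule, clamped
#' to the observed data range: `whisker_low = max(Q1 - 1.5 IQR, min(x))`,
#' `whisker_high = min(Q3 + 1.5 IQR, max(x))`.
#'
#' @param x Non-empty numeric vector.
#' @return Data frame with one row: `n`, `mean`, `median`, `q1`, `q3`,
#'   `iqr`, `whisker_low`, `whisker_high`.
#' @export
summarise_group <- function(x) {
  if (!length(x)) stop("empty input", call. = FALSE)
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  data.frame(n = length(x), mean = mean(x), median = q[2],
             q1 = q[1], q3 = q[3], iqr = iqr,
             whisker_low = max(q[1] - 1.5 * iqr, min(x)),
             whisker_high = min(q[3] + 1.5 * iqr, max(x)))
}

#' Compare channel widths (and base areas) across conditions
#'
#' Pairwise Mann-Whitney U tests between conditions on the widths at each
#' normalised radial position, plus (optionally) on colony base areas, with
#' a boxplot-style summary per group. No multiple-testing correction is
#' applied; p-values below 0.05 are conventionally called significant, a
#' caveat worth keeping in mind when many positions are compared.
#'
#' @param table A combined channel width table for two or more conditions
#'   (rows from [measure_channels()] results, including a `condition`
#'   column; only retained rows should be passed).
#' @param fractions Normalised radial positions at which widths are
#'   compared (fractions of each colony's own largest sampled radius).
#' @param base_areas Optional named list (by condition) of numeric base
#'   area vectors to compare as well.
#' @return List with `tests` (data frame: `measure`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `U`, `p_value`) and `summaries` (data frame of group
#'   summaries per measure and condition).
#' @export
compare_groups <- function(table, fractions = c(0.2, 0.5, 1.0),
                           base_areas = NULL) {
  conds <- unique(table$condition)
  if (length(conds) < 2 && is.null(base_areas)) {
    stop("need at least 2 conditions to compare", call. = FALSE)
  }
  # widths at each normalised position, pooled over the biofilms of a
  # condition (each biofilm contributes its own nearest-grid radius)
  value_sets <- list()
  for (f in fractions) {
    for (cond in conds) {
      sub <- table[table$condition == cond, , drop = FALSE]
      if (!nrow(sub)) stop("condition with no data: ", cond, call. = FALSE)
      vals <- unlist(lapply(split(sub, sub$biofilm_id), function(d) {
        normalised_position_summary(d, f)$widths[[1]]
      }), use.names = FALSE)
      value_sets[[sprintf("width_at_%d%%", round(100 * f))]][[cond]] <- vals
    }
  }
  if (!is.null(base_areas)) value_sets[["base_area"]] <- base_areas
  tests <- list(); summaries <- list()
  for (measure in names(value_sets)) {
    groups <- value_sets[[measure]]
    gn <- names(groups)
    for (g in gn) {
      summaries[[length(summaries) + 1]] <-
        cbind(measure = measure, condition = g, summarise_group(groups[[g]]))
    }
    if (length(gn) >= 2) {
      pairs <- utils::combn(gn, 2)
      for (k in seq_len(ncol(pairs))) {
        res <- mann_whitney_u(groups[[pairs[1, k]]], groups[[pairs[2, k]]])
        tests[[length(tests) + 1]] <- data.frame(
          measure = measure, group_a = pairs[1, k], group_b = pairs[2, k],
          n_a = res$n_a, n_b = res$n_b, U = res$U, p_value = res$p_value)
      }
    }
  }
  list(tests = do.call(rbind, tests), summaries = do.call(rbind, summaries))
}
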