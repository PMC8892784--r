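#' Kendall's tau-b rank correlation
#'
#' Direct pairwise-count implementation with tie correction in both
#' variables, exposed because the JTK-style test below is built on the
#' same concordance counts.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return tau-b in \[-1, 1\] (`NA` when either variable is constant).
#' @export
#' @examples
#' kendall_tau(1:4, c(4, 3, 2, 1))
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  if (length(x) < 2) abort("At least 2 observations are required.")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  s <- sum(sx * sy) / 2
  n <- length(x)
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_pairs(x)
  n2 <- tie_pairs(y)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) return(NA_real_)
  s / denom
}

# ---- JTK-style exact null machinery -------------------------------------

# Coefficients of the Gaussian binomial [m+n choose n]_q: the exact null
# counts of the Mann-Whitney U statistic (u = 0..m*n) for untied data.
gauss_binomial_counts <- function(m, n) {
  co <- 1
  for (i in seq_len(n)) {
    # multiply by (1 - q^(m+i))
    shifted <- c(numeric(m + i), co)
    co <- c(co, numeric(m + i)) - shifted
    # divide by (1 - q^i): out[j] = co[j] + out[j - i]
    out <- numeric(length(co))
    for (j in seq_along(co)) {
      out[j] <- co[j] + if (j > i) out[j - i] else 0
    }
    co <- out
  }
  co[seq_len(m * n + 1)]
}

# Exact null distribution of the Jonckheere-Terpstra concordance count
# against a tied reference with group sizes `t` (data assumed untied):
# JT decomposes into independent Mann-Whitney statistics of each group
# against the pooled earlier groups, so the null is their convolution.
jt_null_distribution <- function(t) {
  dist <- 1
  m <- t[1]
  for (i in seq_along(t)[-1]) {
    dist <- convolve_counts(dist, gauss_binomial_counts(m, t[i]))
    m <- m + t[i]
  }
  dist / sum(dist)
}

convolve_counts <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

# Candidate reference waveforms: one cosine per candidate peak time on
# the observed sampling grid. Lags whose reference rank pattern repeats
# are collapsed for the Bonferroni factor.
jtk_plan <- function(times, period = 24) {
  lags <- sort(unique(times %% period))
  # symmetric cosine values are equal only up to floating error; round
  # so tie groups form correctly
  refs <- lapply(lags, function(lag) {
    round(cos(2 * pi * (times - lag) / period), 9)
  })
  patterns <- vapply(refs, function(r) paste(rank(r), collapse = ","), "")
  keep <- !duplicated(patterns)
  lags <- lags[keep]
  refs <- refs[keep]
  plans <- lapply(refs, function(r) {
    rsign <- sign(outer(r, r, "-"))
    sizes <- as.integer(table(factor(r, levels = sort(unique(r)))))
    total_pairs <- sum(outer(sizes, sizes)[lower.tri(diag(length(sizes)))])
    null <- jt_null_distribution(sizes)
    # upper-tail probabilities P(JT >= k), k = 0..T
    tail <- rev(cumsum(rev(null)))
    list(rsign = rsign, total_pairs = total_pairs, tail = tail, ref = r)
  })
  list(lags = lags, plans = plans, n_patterns = length(lags))
}

#' JTK_CYCLE-style Kendall concordance rhythmicity test
#'
#' Scores Kendall concordance between the observed values and a
#' reference cosine at every candidate peak time on the sampling grid
#' (replicates share the reference value of their timepoint). Each
#' lag's one-sided p-value comes from the exact null distribution of
#' the concordance count for the reference's tie pattern (assuming
#' untied data), computed by dynamic programming; the reported p-value
#' is the minimum over lags times the number of distinct lag patterns
#' (Bonferroni), capped at 1. The phase estimate is the best lag's peak
#' time.
#'
#' @inheritParams harmonic_regression_test
#' @param plan Precomputed lag references for a fixed design (internal
#'   use).
#' @return A one-row tibble; `statistic` is tau-b at the best lag,
#'   `phase` its peak time.
#' @export
jtk_cycle_test <- function(times, values, period = 24, plan = NULL) {
  validate_series(times, values, min_n = 6, min_distinct = 3)
  if (is_constant(values)) {
    return(detector_result("jtk", statistic = NA_real_, p = 1,
                           period = period))
  }
  plan <- plan %||% jtk_plan(times, period)
  ysign <- sign(outer(values, values, "-"))
  p_lag <- numeric(length(plan$lags))
  s_lag <- numeric(length(plan$lags))
  for (k in seq_along(plan$lags)) {
    pl <- plan$plans[[k]]
    s <- sum(pl$rsign * ysign) / 2
    jt <- ceiling((s + pl$total_pairs) / 2)
    jt <- min(max(jt, 0), pl$total_pairs)
    p_lag[k] <- pl$tail[jt + 1]
    s_lag[k] <- s
  }
  best <- which.min(p_lag)
  p <- min(1, p_lag[best] * plan$n_patterns)
  tau <- kendall_tau(values, plan$plans[[best]]$ref)
  detector_result("jtk", statistic = tau, p = p,
                  phase = plan$lags[best] %% period, period = period)
}

# ---- RAIN-style umbrella (Mack-Wolfe) machinery -------------------------

# For candidate peak k among g circularly ordered timepoint groups, the
# umbrella arrangement starts at the opposite (trough) position and
# rises to the peak at position h = g - floor(g/2) + 1.
umbrella_arrangement <- function(g, k) {
  off <- floor(g / 2)
  idx <- ((k - 1 + off + seq_len(g) - 1) %% g) + 1
  list(order = idx, h = g - off + 1L)
}

mack_wolfe_moments <- function(sizes, h) {
  n1 <- sum(sizes[seq_len(h)])
  n2 <- sum(sizes[h:length(sizes)])
  n <- sum(sizes)
  nh <- sizes[h]
  mean_a <- (n1^2 + n2^2 - sum(sizes^2) - nh^2) / 4
  var_a <- (2 * (n1^3 + n2^3) + 3 * (n1^2 + n2^2) -
              sum(sizes^2 * (2 * sizes + 3)) - nh^2 * (2 * nh + 3) +
              12 * nh * n1 * n2 - 12 * nh^2 * n) / 72
  list(mean = mean_a, var = var_a)
}

rain_plan <- function(times, period = 24) {
  ut <- sort(unique(times %% period))
  g <- length(ut)
  groups <- lapply(ut, function(t0) which((times %% period) == t0))
  sizes_by_group <- lengths(groups)
  peaks <- lapply(seq_len(g), function(k) {
    arr <- umbrella_arrangement(g, k)
    sizes <- sizes_by_group[arr$order]
    mom <- mack_wolfe_moments(sizes, arr$h)
    list(order = arr$order, h = arr$h, mean = mom$mean, var = mom$var)
  })
  list(ut = ut, groups = groups, peaks = peaks, g = g,
       n = length(times))
}

# Pairwise Mann-Whitney counts U[i, j] = #{a in group i, b in group j :
# X_a < X_b}, ties counted 1/2; computed once per gene, reused by every
# candidate peak.
pairwise_mw_counts <- function(values, groups) {
  g <- length(groups)
  U <- matrix(0, g, g)
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      d <- outer(values[groups[[i]]], values[groups[[j]]], "-")
      U[i, j] <- sum(d < 0) + 0.5 * sum(d == 0)
      U[j, i] <- sum(d > 0) + 0.5 * sum(d == 0)
    }
  }
  U
}

#' RAIN-style umbrella rank rhythmicity test
#'
#' For each candidate peak time on the sampling grid, scores the
#' Mack-Wolfe peak-known umbrella statistic over the circular
#' rise-then-fall arrangement of timepoint groups (replicates are the
#' within-group observations). Per-peak p-values use the normal
#' approximation with a tie-corrected variance; the reported p-value is
#' the minimum times the number of candidate peaks (Bonferroni), capped
#' at 1. Ties in the best statistic resolve toward the latest peak
#' time.
#'
#' @inheritParams jtk_cycle_test
#' @return A one-row tibble; `statistic` is the best Mack-Wolfe
#'   statistic, `phase` the best peak time.
#' @export
rain_test <- function(times, values, period = 24, plan = NULL) {
  validate_series(times, values, min_n = 6, min_distinct = 3)
  if (is_constant(values)) {
    return(detector_result("rain", statistic = NA_real_, p = 1,
                           period = period))
  }
  plan <- plan %||% rain_plan(times, period)
  U <- pairwise_mw_counts(values, plan$groups)
  tie_factor <- rank_tie_correction(values)
  p_peak <- numeric(plan$g)
  a_peak <- numeric(plan$g)
  for (k in seq_len(plan$g)) {
    pk <- plan$peaks[[k]]
    ord <- pk$order
    h <- pk$h
    a <- 0
    for (i in seq_len(h - 1)) {
      for (j in (i + 1):h) a <- a + U[ord[i], ord[j]]
    }
    for (i in h:(plan$g - 1)) {
      for (j in (i + 1):plan$g) a <- a + U[ord[j], ord[i]]
    }
    v <- pk$var * tie_factor
    p_peak[k] <- if (v <= 0) 1 else pnorm((a - pk$mean) / sqrt(v),
                                          lower.tail = FALSE)
    a_peak[k] <- a
  }
  best <- which(p_peak == min(p_peak))
  best <- best[length(best)]
  p <- min(1, p_peak[best] * plan$g)
  detector_result("rain", statistic = a_peak[best], p = p,
                  phase = plan$ut[best], period = period)
}

rank_tie_correction <- function(values) {
  n <- length(values)
  t <- table(values)
  1 - sum(t^3 - t) / (n^3 - n)
}
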