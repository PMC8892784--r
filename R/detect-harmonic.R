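# Shared validation for detector inputs. Repeated time values are the
# norm (three animals per ZT); constant series short-circuit to p = 1 so
# downstream Fisher combination stays defined.
validate_series <- function(times, values, min_n = 4, min_distinct = 3) {
  if (length(times) != length(values)) {
    abort("`times` and `values` must have the same length.")
  }
  if (length(values) < min_n) {
    abort(sprintf("At least %d observations are required.", min_n))
  }
  if (length(unique(times)) < min_distinct) {
    abort(sprintf("At least %d distinct timepoints are required.",
                  min_distinct))
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    abort("Times and values must be finite; missing data are not supported.")
  }
  invisible(TRUE)
}

detector_result <- function(method, statistic, p, phase = NA_real_,
                            amplitude = NA_real_, mesor = NA_real_,
                            period = NA_real_) {
  tibble(method = method, statistic = statistic, p = p, phase = phase,
         amplitude = amplitude, mesor = mesor, period = period)
}

is_constant <- function(values) {
  diff(range(values)) <= .Machine$double.eps * max(1, abs(values[1])) * 8
}

# Core cosinor least squares, shared by the harmonic and ARSER paths.
# Returns coefficients, fitted amplitude/phase, and the F test of the
# two harmonic terms against the intercept-only model, df (2, n - 3).
cosinor_fit <- function(times, values, period) {
  n <- length(values)
  omega <- 2 * pi / period
  X <- cbind(1, cos(omega * times), sin(omega * times))
  fit <- stats::lm.fit(X, values)
  cf <- fit$coefficients
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((values - mean(values))^2)
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  p <- if (!is.finite(fstat)) 0 else pf(fstat, 2, n - 3, lower.tail = FALSE)
  amplitude <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- (atan2(cf[3], cf[2]) / omega) %% period
  list(mesor = unname(cf[1]), amplitude = unname(amplitude),
       phase = unname(phase), fstat = unname(fstat), p = unname(p),
       rss = rss1)
}

#' Cosinor harmonic regression rhythmicity test
#'
#' Least-squares fit of `y = m + a*cos(wt) + b*sin(wt)` with
#' `w = 2*pi/period`. The amplitude is `sqrt(a^2 + b^2)`, the phase is
#' the fitted peak time in hours, and the p-value comes from the F
#' statistic with (2, n - 3) degrees of freedom comparing the full
#' model against the intercept-only model. Constant input returns
#' p = 1 with amplitude 0.
#'
#' @param times Observation times in hours; repeated values allowed.
#' @param values Expression values, same length as `times`.
#' @param period Target period in hours (default 24).
#' @return A one-row tibble with columns `method`, `statistic` (F),
#'   `p`, `phase`, `amplitude`, `mesor`, `period`.
#' @export
#' @examples
#' t <- rep(c(1, 5, 9, 13, 17, 21), each = 3)
#' y <- 10 + 3 * cos(2 * pi * (t - 9) / 24)
#' harmonic_regression_test(t, y)
harmonic_regression_test <- function(times, values, period = 24) {
  validate_series(times, values, min_n = 4, min_distinct = 3)
  if (is_constant(values)) {
    return(detector_result("harmonic", statistic = 0, p = 1,
                           amplitude = 0, mesor = values[1],
                           period = period))
  }
  fit <- cosinor_fit(times, values, period)
  detector_result("harmonic", statistic = fit$fstat, p = fit$p,
                  phase = fit$phase, amplitude = fit$amplitude,
                  mesor = fit$mesor, period = period)
}

# Lomb-Scargle machinery. The plan precomputes, for each scanned
# frequency, the tau-shifted cosine/sine bases and their sums of
# squares, which depend only on the sampling times.
ls_plan <- function(times, period_range = c(20, 28), n_freq = 25) {
  periods <- seq(period_range[1], period_range[2], length.out = n_freq)
  omegas <- 2 * pi / periods
  C <- matrix(0, n_freq, length(times))
  S <- matrix(0, n_freq, length(times))
  cc <- numeric(n_freq)
  ss <- numeric(n_freq)
  for (k in seq_len(n_freq)) {
    w <- omegas[k]
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    C[k, ] <- cos(w * (times - tau))
    S[k, ] <- sin(w * (times - tau))
    cc[k] <- sum(C[k, ]^2)
    ss[k] <- sum(S[k, ]^2)
  }
  # Horne-Baliunas effective number of independent frequencies in the
  # scanned band: span x bandwidth, at least 1. A narrow 20-28 h band
  # over a single sampled cycle holds fewer independent frequencies
  # than grid points, and exponentiating by the raw grid size would
  # make the test essentially powerless.
  span <- diff(range(times))
  m_indep <- max(1, ceiling(span * (1 / period_range[1] -
                                      1 / period_range[2])))
  list(periods = periods, C = C, S = S, cc = cc, ss = ss,
       n_freq = n_freq, m_indep = m_indep)
}

ls_power <- function(values, plan) {
  yc <- values - mean(values)
  s2 <- stats::var(values)
  num_c <- as.vector(plan$C %*% yc)^2 / plan$cc
  num_s <- as.vector(plan$S %*% yc)^2 / pmax(plan$ss, 1e-12)
  (num_c + num_s) / (2 * s2)
}

#' Lomb-Scargle periodogram rhythmicity test
#'
#' Scans the classical variance-normalized Lomb-Scargle power over a
#' grid of candidate periods (default 20-28 h, 25 grid points) and
#' reports the maximum. Significance follows the Horne-Baliunas
#' construction `p = 1 - (1 - exp(-z_max))^M` with `M` the effective
#' number of independent frequencies in the scanned band (observation
#' span times bandwidth, at least 1). On evenly spaced single-replicate data the
#' power at an exact Fourier period equals the classical periodogram
#' power.
#'
#' @inheritParams harmonic_regression_test
#' @param period_range Period search window in hours.
#' @param n_freq Number of grid frequencies (at least 24).
#' @param plan Optional precomputed grid from repeated calls on a fixed
#'   design (internal use).
#' @return A one-row tibble; `statistic` is the peak normalized power,
#'   `period` the maximizing period.
#' @export
lomb_scargle_test <- function(times, values, period = 24,
                              period_range = c(20, 28), n_freq = 25,
                              plan = NULL) {
  validate_series(times, values, min_n = 4, min_distinct = 3)
  if (is_constant(values)) {
    return(detector_result("lomb_scargle", statistic = 0, p = 1))
  }
  plan <- plan %||% ls_plan(times, period_range, n_freq)
  z <- ls_power(values, plan)
  k <- which.max(z)
  zmax <- z[k]
  # 1 - (1 - e^-z)^M, evaluated stably for large z
  p <- -expm1(plan$m_indep * log1p(-exp(-zmax)))
  p <- min(max(p, 0), 1)
  detector_result("lomb_scargle", statistic = zmax, p = p,
                  period = plan$periods[k])
}

#' ARSER-style autoregressive spectral rhythmicity test
#'
#' Replicates are averaged per timepoint, the mean profile is linearly
#' detrended, and a Yule-Walker autoregressive model (order chosen by
#' AIC up to `round(n/4)`) estimates the spectral density. The dominant
#' period inside `period_range` is selected (falling back to the target
#' period when the spectrum has no interior peak), and the detrended
#' profile is then tested by cosinor harmonic regression at the
#' selected period, with the p-value from the same F test as
#' [harmonic_regression_test()].
#'
#' @inheritParams harmonic_regression_test
#' @param period_range Period search window in hours; collapse it to a
#'   single value (e.g. `c(24, 24)`) to pin the period.
#' @param detrend Remove a linear trend from the mean profile first.
#' @return A one-row tibble; `period` is the selected period.
#' @export
arser_test <- function(times, values, period = 24,
                       period_range = c(20, 28), detrend = TRUE) {
  validate_series(times, values, min_n = 6, min_distinct = 4)
  prof <- profile_means(times, values)
  if (is_constant(prof$y)) {
    return(detector_result("arser", statistic = 0, p = 1, amplitude = 0,
                           mesor = prof$y[1], period = period))
  }
  y <- prof$y
  if (detrend) {
    # slope estimated jointly with the target-period harmonic so a pure
    # cosine is not distorted (trend and harmonic are not orthogonal on
    # a short profile); the AR period search runs on the slope-removed
    # series, and the final F test keeps the trend in the model
    omega <- 2 * pi / period
    X <- cbind(1, prof$t, cos(omega * prof$t), sin(omega * prof$t))
    slope <- stats::lm.fit(X, y)$coefficients[2]
    y_d <- y - slope * prof$t
  } else {
    y_d <- y
  }
  if (is_constant(y_d)) {
    # pure linear trend: nothing rhythmic left after detrending
    return(detector_result("arser", statistic = 0, p = 1, amplitude = 0,
                           mesor = mean(prof$y), period = period))
  }
  sel <- if (diff(period_range) <= 0) {
    period_range[1]
  } else {
    ar_dominant_period(y_d, dt = prof$dt, period_range = period_range,
                       fallback = period)
  }
  fit <- if (detrend) {
    cosinor_trend_fit(prof$t, prof$y, sel)
  } else {
    cosinor_fit(prof$t, y_d, sel)
  }
  detector_result("arser", statistic = fit$fstat, p = fit$p,
                  phase = fit$phase, amplitude = fit$amplitude,
                  mesor = mean(prof$y), period = sel)
}

# Cosinor with a linear-trend nuisance term: F tests the two harmonic
# coefficients of {1, t, cos, sin} against the reduced model {1, t},
# df (2, n - 4), so the estimated slope costs its degree of freedom.
cosinor_trend_fit <- function(times, values, period) {
  n <- length(values)
  omega <- 2 * pi / period
  X <- cbind(1, times, cos(omega * times), sin(omega * times))
  full <- stats::lm.fit(X, values)
  red <- stats::lm.fit(X[, 1:2, drop = FALSE], values)
  rss1 <- sum(full$residuals^2)
  rss0 <- sum(red$residuals^2)
  scale <- sum(values^2) + 1
  if (rss0 <= .Machine$double.eps * scale) {
    return(list(mesor = mean(values), amplitude = 0, phase = NA_real_,
                fstat = 0, p = 1, rss = rss1))
  }
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 4))
  p <- if (!is.finite(fstat)) 0 else pf(fstat, 2, n - 4, lower.tail = FALSE)
  cf <- full$coefficients
  amplitude <- sqrt(cf[3]^2 + cf[4]^2)
  phase <- (atan2(cf[4], cf[3]) / omega) %% period
  list(mesor = unname(cf[1]), amplitude = unname(amplitude),
       phase = unname(phase), fstat = unname(fstat), p = unname(p),
       rss = rss1)
}

profile_means <- function(times, values) {
  ut <- sort(unique(times))
  y <- vapply(ut, function(t0) mean(values[times == t0]), 0)
  dts <- diff(ut)
  list(t = ut, y = y, dt = dts[1],
       even = length(unique(round(dts, 9))) == 1)
}

# Yule-Walker AR spectrum scanned over a fine period grid; a grid
# argmax sitting on the window boundary is treated as "no peak".
ar_dominant_period <- function(y, dt, period_range, fallback) {
  order_max <- max(1, round(length(y) / 4))
  fit <- tryCatch(
    stats::ar(y, aic = TRUE, order.max = order_max, method = "yule-walker"),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$order == 0) return(fallback)
  grid <- seq(period_range[1], period_range[2], by = 0.1)
  phi <- fit$ar
  dens <- vapply(grid, function(P) {
    f <- dt / P  # cycles per sampling step
    z <- exp(-2i * pi * f * seq_along(phi))
    1 / Mod(1 - sum(phi * z))^2
  }, 0)
  k <- which.max(dens)
  if (k == 1 || k == length(grid)) return(fallback)
  grid[k]
}

# F24 spectral machinery: single-sided power of the per-timepoint mean
# profile via cosine/sine projections (conjugate bins folded in).
f24_plan <- function(times, period = 24) {
  ut <- sort(unique(times))
  nt <- length(ut)
  if (nt < 3) abort("F24 needs at least 3 distinct timepoints.")
  dts <- unique(round(diff(ut), 9))
  if (length(dts) != 1) {
    abort("F24 requires evenly spaced timepoints.")
  }
  if (abs(nt * dts - period) > 1e-8) {
    abort("F24 requires the timepoints to span exactly one period.")
  }
  # group-mean operator: samples -> per-timepoint means
  G <- t(vapply(ut, function(t0) (times == t0) / sum(times == t0),
                numeric(length(times))))
  kmax <- floor(nt / 2)
  idx <- seq_len(nt) - 1
  cosb <- t(vapply(seq_len(kmax),
                   function(k) cos(2 * pi * k * idx / nt), numeric(nt)))
  sinb <- t(vapply(seq_len(kmax),
                   function(k) sin(2 * pi * k * idx / nt), numeric(nt)))
  # fold weight: interior bins have a conjugate partner, Nyquist does not
  fold <- ifelse(seq_len(kmax) < nt / 2, 2, 1)
  list(G = G, cosb = cosb, sinb = sinb, fold = fold, nt = nt)
}

f24_statistic <- function(values, plan) {
  prof <- as.vector(plan$G %*% values)
  a <- as.vector(plan$cosb %*% prof)
  b <- as.vector(plan$sinb %*% prof)
  pw <- plan$fold * (a^2 + b^2)
  total <- sum(pw)
  if (total <= .Machine$double.eps * sum(prof^2 + 1)) return(NA_real_)
  pw[1] / total
}

#' F24 spectral power-fraction rhythmicity test
#'
#' Averages replicates per timepoint, Fourier-decomposes the mean
#' profile, and scores the fraction of non-DC spectral power carried by
#' the fundamental (24 h) component: 1 for a pure 24 h cosine, 0 for a
#' pure 12 h harmonic. Significance is assessed by permuting timepoint
#' assignments of the raw observations (`p = (1 + #{perm >= obs}) /
#' (1 + n_perm)`). A constant profile has no defined power fraction and
#' returns p = 1.
#'
#' @inheritParams harmonic_regression_test
#' @param n_perm Number of label permutations.
#' @param seed Optional seed making the permutation p-value exactly
#'   reproducible; when `NULL` the current RNG stream is used.
#' @param plan,perms Precomputed spectral plan and permutation index
#'   matrix for repeated calls on a fixed design (internal use).
#' @return A one-row tibble; `statistic` is the observed power fraction.
#' @export
f24_test <- function(times, values, period = 24, n_perm = 10000,
                     seed = NULL, plan = NULL, perms = NULL) {
  validate_series(times, values, min_n = 6, min_distinct = 3)
  plan <- plan %||% f24_plan(times, period)
  obs <- f24_statistic(values, plan)
  if (is.na(obs)) {
    return(detector_result("f24", statistic = NA_real_, p = 1,
                           period = period))
  }
  n <- length(values)
  if (is.null(perms)) {
    draw <- function() matrix(replicate(n_perm, sample.int(n)), nrow = n)
    perms <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  null_stats <- f24_null_stats(values, plan, perms)
  p <- (1 + sum(null_stats >= obs, na.rm = TRUE)) / (1 + ncol(perms))
  detector_result("f24", statistic = obs, p = p, period = period)
}

f24_null_stats <- function(values, plan, perms) {
  permuted <- matrix(values[perms], nrow = nrow(perms))
  prof <- plan$G %*% permuted
  a <- plan$cosb %*% prof
  b <- plan$sinb %*% prof
  pw <- plan$fold * (a^2 + b^2)
  total <- colSums(pw)
  out <- pw[1, ] / total
  out[total <= .Machine$double.eps] <- NA_real_
  out
}
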