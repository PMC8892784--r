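test_that("harmonic regression recovers a noise-free cosinor exactly", {
  s <- cosine_series(mesor = 10, amplitude = 3, phase = 9)
  fit <- harmonic_regression_test(s$t, s$y)
  expect_equal(fit$phase, 9, tolerance = 1e-8)
  expect_equal(fit$amplitude, 3, tolerance = 1e-8)
  expect_equal(fit$mesor, 10, tolerance = 1e-8)
  expect_lt(fit$p, 1e-10)
})

test_that("constant series yield p = 1 across detectors", {
  t <- design_times()
  y <- rep(5, 18)
  expect_equal(harmonic_regression_test(t, y)$p, 1)
  expect_equal(harmonic_regression_test(t, y)$amplitude, 0)
  expect_equal(lomb_scargle_test(t, y)$p, 1)
  expect_equal(jtk_cycle_test(t, y)$p, 1)
  expect_equal(rain_test(t, y)$p, 1)
  expect_equal(arser_test(t, y)$p, 1)
  expect_equal(f24_test(t, y, n_perm = 50, seed = 1)$p, 1)
})

test_that("harmonic phase estimates are shift-equivariant and p scale-free", {
  set.seed(42)
  t <- design_times()
  for (i in 1:10) {
    y <- (8 + 2 * cos(2 * pi * (t - runif(1, 0, 24)) / 24)) *
      exp(rnorm(18, 0, 0.15))
    base <- harmonic_regression_test(t, y)
    delta <- runif(1, 0, 24)
    shifted <- harmonic_regression_test(t + delta, y)
    expect_equal(circ_diff(shifted$phase, (base$phase + delta) %% 24), 0,
                 tolerance = 1e-6)
    scaled <- harmonic_regression_test(t, 3.7 * y + 11)
    expect_equal(scaled$p, base$p, tolerance = 1e-9)
  }
})

test_that("detector p-values are invariant to affine value transforms", {
  set.seed(7)
  t <- design_times()
  y <- 10 * exp(rnorm(18, 0, 0.2))
  y2 <- 2.5 * y + 4
  expect_equal(lomb_scargle_test(t, y2)$p, lomb_scargle_test(t, y)$p,
               tolerance = 1e-9)
  expect_equal(jtk_cycle_test(t, y2)$p, jtk_cycle_test(t, y)$p)
  expect_equal(rain_test(t, y2)$p, rain_test(t, y)$p, tolerance = 1e-9)
  expect_equal(arser_test(t, y2)$p, arser_test(t, y)$p, tolerance = 1e-6)
  perms <- withr::with_seed(3, matrix(replicate(200, sample.int(18)), 18))
  plan <- rhythmshift:::f24_plan(t, 24)
  expect_equal(f24_test(t, y2, plan = plan, perms = perms)$p,
               f24_test(t, y, plan = plan, perms = perms)$p)
})

test_that("null harmonic p-values are uniform", {
  set.seed(1234)
  t <- design_times()
  ps <- vapply(1:5000, function(i) {
    harmonic_regression_test(t, rnorm(18, 10, 1))$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Lomb-Scargle power matches the classical periodogram on even single-replicate sampling", {
  t <- c(1, 5, 9, 13, 17, 21)
  set.seed(5)
  for (i in 1:20) {
    y <- 5 + 2 * cos(2 * pi * (t - runif(1, 0, 24)) / 24) + rnorm(6, 0, 0.5)
    plan <- rhythmshift:::ls_plan(t, period_range = c(24, 24), n_freq = 1)
    z <- rhythmshift:::ls_power(y, plan)
    w <- 2 * pi / 24
    yc <- y - mean(y)
    classical <- (sum(yc * cos(w * t))^2 + sum(yc * sin(w * t))^2) /
      (length(y) * stats::var(y))
    expect_equal(z, classical, tolerance = 1e-9)
  }
})

test_that("Lomb-Scargle maximizes near 24 h on clean data", {
  s <- cosine_series()
  fit <- lomb_scargle_test(s$t, s$y)
  expect_lt(abs(fit$period - 24), 0.5)
  expect_lt(fit$p, 0.01)
})

test_that("ARSER selects the true period and nulls out pure trends", {
  s <- cosine_series()
  fit <- arser_test(s$t, s$y)
  expect_lt(abs(fit$period - 24), 0.5)
  expect_lt(fit$p, 1e-6)
  expect_equal(circ_diff(fit$phase, 9), 0, tolerance = 1e-6)

  trend <- arser_test(s$t, 2 + 0.3 * s$t)
  expect_gt(trend$p, 0.5)
})

test_that("ARSER with pinned period and no detrending equals harmonic regression on the mean profile", {
  set.seed(6)
  t <- design_times()
  for (i in 1:10) {
    y <- (10 + 3 * cos(2 * pi * (t - 7) / 24)) * exp(rnorm(18, 0, 0.2))
    pinned <- arser_test(t, y, period_range = c(24, 24), detrend = FALSE)
    ut <- sort(unique(t))
    prof <- vapply(ut, function(t0) mean(y[t == t0]), 0)
    ref <- harmonic_regression_test(ut, prof)
    expect_equal(pinned$p, ref$p, tolerance = 1e-12)
    expect_equal(pinned$amplitude, ref$amplitude, tolerance = 1e-12)
  }
})

test_that("F24 concentrates power correctly and is reproducible", {
  t <- design_times()
  pure24 <- 5 + cos(2 * pi * t / 24)
  pure12 <- 5 + cos(2 * pi * t / 12)
  expect_equal(f24_test(t, pure24, n_perm = 50, seed = 1)$statistic, 1,
               tolerance = 1e-12)
  expect_equal(f24_test(t, pure12, n_perm = 50, seed = 1)$statistic, 0,
               tolerance = 1e-12)
  set.seed(99)
  y <- 10 * exp(rnorm(18, 0, 0.2))
  p1 <- f24_test(t, y, n_perm = 2000, seed = 77)$p
  p2 <- f24_test(t, y, n_perm = 2000, seed = 77)$p
  expect_identical(p1, p2)
})

test_that("detectors reject inputs that are too small", {
  expect_error(harmonic_regression_test(c(1, 5, 9), c(1, 2, 3)), "4")
  expect_error(jtk_cycle_test(c(1, 5, 9, 13), c(1, 2, 3, 4)), "6")
  expect_error(rain_test(c(1, 5), c(1, 2)), "6")
  expect_error(kendall_tau(1:3, 1:4), "length")
})
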