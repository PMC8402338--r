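test_that("series normalisation divides by the smoothed total", {
  expect_equal(normalize_series(c(0, 10, 0), c(10, 10, 10), 1)$values,
               c(0, 1, 0))
  # constant totals: output = raw / c for any window
  raw <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(normalize_series(raw, rep(4, 8), 5)$values, raw / 4)
  # raw = totals, constant: output is exactly 1 everywhere
  expect_equal(normalize_series(rep(7, 6), rep(7, 6), 3)$values, rep(1, 6))
  expect_error(normalize_series(1:3, c(1, 0, 5), 1), "bin 2")
  expect_error(normalize_series(1:3, 1:4, 1), "equal length")
})

test_that("peak detection finds isolated bursts and obeys the merge rule", {
  expect_equal(nrow(detect_peaks(rep(5, 100))), 0)       # constant: none
  x <- rep(1, 10000); x[5000] <- 101                     # delta on background 1
  pk <- detect_peaks(x, background_window = 21, threshold_factor = 5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, 5000)
  expect_equal(pk$relative_height, 100, tolerance = 0.02)
  # merge rule around min_separation
  y <- numeric(500); y[100] <- 50; y[100 + 2] <- 40     # gap < min_sep = 3
  expect_equal(nrow(detect_peaks(y, min_separation = 3)), 1)
  z <- numeric(500); z[100] <- 50; z[100 + 4] <- 40     # gap > min_sep
  expect_equal(nrow(detect_peaks(z, min_separation = 3)), 2)
  expect_error(detect_peaks(1:5, background_window = 21), "shorter")
})

test_that("peak detection is invariant under positive rescaling", {
  set.seed(10)
  v <- rpois(2000, 1)
  v[sample(2000, 12)] <- v[sample(2000, 12)] + rlnorm(12, 4, 0.5)
  a <- detect_peaks(v)
  b <- detect_peaks(v * 73.1)
  expect_equal(a$position, b$position)
  expect_equal(a$relative_height, b$relative_height)
})

test_that("peak statistics compute separations with the optional gap filter", {
  x <- numeric(200); x[c(10, 30, 70)] <- 100
  pk <- detect_peaks(x, background_window = 5)
  expect_equal(pk$position, c(10, 30, 70))
  ps <- peak_statistics(pk)
  expect_equal(ps$separations, c(20, 40))
  expect_equal(peak_statistics(pk, min_gap = 25)$separations, 40)
  one <- detect_peaks(c(numeric(99), 100, numeric(100)), background_window = 5)
  expect_equal(nrow(one), 1)
  expect_length(peak_statistics(one)$separations, 0)
})

test_that("lognormal fit recovers known parameters and degenerates cleanly", {
  set.seed(4)
  x <- exp(rnorm(1e4, 1.0, 0.5))
  f <- fit_lognormal(x)
  expect_equal(unname(f$parameters["meanlog"]), 1.0, tolerance = 0.02)
  expect_equal(unname(f$parameters["sdlog"]), 0.5, tolerance = 0.02)
  expect_lt(f$gof$ks, 0.02)
  # scale invariance: k * samples shifts meanlog by log(k), sdlog unchanged
  f2 <- fit_lognormal(3 * x)
  expect_equal(unname(f2$parameters["meanlog"]),
               unname(f$parameters["meanlog"]) + log(3))
  expect_equal(unname(f2$parameters["sdlog"]), unname(f$parameters["sdlog"]))
  fd <- fit_lognormal(rep(2.5, 10))
  expect_true(fd$degenerate)
  expect_equal(unname(fd$parameters["meanlog"]), log(2.5))
  expect_equal(unname(fd$parameters["sdlog"]), 0)
  expect_error(fit_lognormal(c(1, 2, -1, 3, 4, 5)), "positive")
  expect_error(fit_lognormal(c(1, 2, 3)), "at least 5")
})

test_that("the internal KS distance agrees with stats::ks.test", {
  set.seed(5)
  x <- rlnorm(300, 0.5, 0.8)
  d_pkg <- avburst:::ks_distance(x, function(q) plnorm(q, 0.5, 0.8))
  d_ref <- unname(suppressWarnings(
    ks.test(x, "plnorm", 0.5, 0.8))$statistic)
  expect_equal(d_pkg, d_ref)
  y <- rlnorm(200, 0.7, 0.8)
  expect_equal(avburst:::ks_distance2(x, y),
               unname(suppressWarnings(ks.test(x, y))$statistic))
})

test_that("bounded power-law fits recover known exponents by both methods", {
  set.seed(6)
  x1 <- rpowerlaw_bounded(1e4, -0.75, 10, 20000)
  m1 <- fit_powerlaw_bounded(x1, 10, 20000)
  l1 <- fit_powerlaw_bounded(x1, 10, 20000, method = "logbin_ls")
  expect_equal(unname(m1$parameters["exponent"]), -0.75, tolerance = 0.07)
  expect_equal(unname(l1$parameters["exponent"]), -0.75, tolerance = 0.07)
  x2 <- rpowerlaw_bounded(1e4, -2, 1, 1e4)
  m2 <- fit_powerlaw_bounded(x2, 1, 1e4)
  l2 <- suppressWarnings(fit_powerlaw_bounded(x2, 1, 1e4,
                                              method = "logbin_ls"))
  expect_equal(unname(m2$parameters["exponent"]), -2, tolerance = 0.025)
  expect_equal(unname(l2$parameters["exponent"]), -2, tolerance = 0.1)
  # uniform samples are a bounded power law with exponent 0
  set.seed(7)
  u <- runif(5e3, 5, 50)
  expect_equal(unname(fit_powerlaw_bounded(u, 5, 50)$parameters["exponent"]),
               0, tolerance = 0.05)
  expect_error(fit_powerlaw_bounded(x1, 30, 20), "xmin")
  expect_error(fit_powerlaw_bounded(c(0.5, x1), 1, 20000), "within")
})

test_that("truncated-MLE exponent matches an independent brute-force search", {
  # independent oracle: grid search over the exponent with the normalising
  # constant obtained by numerical integration
  brute <- function(x, xmin, xmax) {
    grid <- seq(-3, 1, by = 0.01)
    ll <- vapply(grid, function(g) {
      z <- integrate(function(t) t^g, xmin, xmax)$value
      sum(g * log(x)) - length(x) * log(z)
    }, numeric(1))
    grid[which.max(ll)]
  }
  set.seed(8)
  for (g_true in c(-0.75, -1.5, 0.3)) {
    x <- rpowerlaw_bounded(3000, g_true, 5, 5000)
    g_fit <- unname(fit_powerlaw_bounded(x, 5, 5000)$parameters["exponent"])
    expect_lt(abs(g_fit - brute(x, 5, 5000)), 0.011)
  }
})

test_that("log-Cauchy fit recovers location and scale", {
  set.seed(9)
  x <- exp(rcauchy(1e4, 2, 0.5))
  x <- x[x > 0 & is.finite(x)]  # drop rare tail draws where exp() under/overflows
  f <- fit_logcauchy(x)
  expect_equal(unname(f$parameters["location"]), 2, tolerance = 0.05)
  expect_equal(unname(f$parameters["scale"]), 0.5, tolerance = 0.1)
  # symmetric log-samples centre the location at the median
  y <- exp(c(1 - (1:50) / 10, 1 + (1:50) / 10, 1))
  fy <- fit_logcauchy(y)
  expect_equal(unname(fy$parameters["location"]), 1, tolerance = 0.02)
  expect_true(fit_logcauchy(rep(3, 25))$degenerate)
  expect_error(fit_logcauchy(c(-1, rep(2, 24))), "positive")
})

test_that("time-rescaling match finds the conversion factor", {
  set.seed(11)
  s <- rlnorm(300, 4, 0.5)
  grid <- seq(0.5, 20, by = 0.5)
  m1 <- rescale_time_match(s, 4.5 * s, grid)
  expect_equal(m1$factor, 4.5)
  expect_equal(m1$ks, 0)
  expect_equal(rescale_time_match(s, s, grid)$factor, 1)
  ref <- 15 * rlnorm(300, 4, 0.5)   # independent draws, same generator
  m3 <- rescale_time_match(s, ref, grid)
  expect_lte(abs(m3$factor - 15), 0.5 + 1e-9)
})

test_that("synthetic burst fixtures carry usable ground truth", {
  set.seed(12)
  fx <- generate_synthetic_bursts(n_peaks = 3, background_rate = 0,
                                  gap_meanlog = 4, length = 300)
  expect_equal(sum(fx$series$values > 0), 3)   # exactly the true peaks
  expect_equal(which(fx$series$values > 0), fx$peaks$position)
  expect_warning(
    generate_synthetic_bursts(n_peaks = 30, gap_meanlog = 4, length = 100),
    "truncated")
})

test_that("detector recovers generated peaks and their gap distribution", {
  set.seed(13)
  hits <- 0; total <- 0
  all_seps <- numeric(0)
  for (i in 1:30) {
    fx <- suppressWarnings(
      generate_synthetic_bursts(n_peaks = 12, height_meanlog = 4,
                                height_sdlog = 0.5, gap_meanlog = 4.2,
                                gap_sdlog = 0.4, background_rate = 1,
                                length = 1200))
    pk <- detect_peaks(fx$series)
    total <- total + nrow(fx$peaks)
    hits <- hits + sum(vapply(fx$peaks$position, function(pos) {
      any(abs(pk$position - pos) <= 1)
    }, logical(1)))
    all_seps <- c(all_seps, peak_statistics(pk)$separations)
  }
  expect_gte(hits / total, 0.95)
  gap_fit <- fit_lognormal(all_seps)
  expect_equal(unname(gap_fit$parameters["meanlog"]), 4.2, tolerance = 0.1)
})
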