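# Burst statistics for activity time series: peak detection over a rolling
# background, the distribution fits used to characterise peak heights and
# separations (lognormal), transition times (bounded power law) and thread
# decay (log-Cauchy), and the time-rescaling match between simulated and
# reference separations.

#' Construct an activity time series
#'
#' Light container for a binned activity series (one non-negative count or
#' rate per bin).
#'
#' @param values Numeric vector of non-negative values.
#' @param bin_width Time units per bin (default 1).
#' @param label Optional label.
#' @return An object of class `av_series`.
#' @export
av_series <- function(values, bin_width = 1, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("series must have length >= 1")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("series values must be finite and non-negative")
  }
  if (bin_width <= 0) stop("bin_width must be > 0")
  structure(list(values = values, bin_width = as.numeric(bin_width),
                 label = as.character(label)), class = "av_series")
}

as_av_series <- function(x, bin_width = 1) {
  if (inherits(x, "av_series")) x else av_series(x, bin_width = bin_width)
}

#' @export
print.av_series <- function(x, ...) {
  cat(sprintf("<av_series> %d bins x %g time units%s\n", length(x$values),
              x$bin_width,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

# centered moving average with shrunken windows at the edges
moving_average <- function(x, window) {
  n <- length(x)
  h <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# centered rolling median with shrunken windows at the edges
rolling_median <- function(x, window) {
  n <- length(x)
  h <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    stats::median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Normalise an activity series by a smoothed total
#'
#' Divides a raw activity series bin-by-bin by the centred moving average
#' of a total-activity series, turning absolute counts into relative
#' interest (useful when the overall traffic of the platform grows over
#' time).  Edge bins use shrunken windows.
#'
#' @param raw,totals Series (numeric or [av_series()]) of equal length.
#' @param smoothing_window Moving-average window in bins.
#' @return An `av_series` of normalised values.
#' @examples
#' normalize_series(c(0, 10, 0), c(10, 10, 10), smoothing_window = 1)
#' @export
normalize_series <- function(raw, totals, smoothing_window) {
  raw <- as_av_series(raw)
  totals <- as_av_series(totals, bin_width = raw$bin_width)
  if (length(raw$values) != length(totals$values)) {
    stop("`raw` and `totals` must have equal length")
  }
  sm <- moving_average(totals$values, smoothing_window)
  bad <- which(sm <= 0)
  if (length(bad)) {
    stop(sprintf("smoothed total is not positive at bin %d", bad[1]))
  }
  av_series(raw$values / sm, bin_width = raw$bin_width,
            label = if (nzchar(raw$label)) paste0(raw$label, " (normalised)")
                    else "")
}

#' Detect activity peaks over a rolling-median background
#'
#' A bin is a peak candidate when its value exceeds `threshold_factor`
#' times the local background, defined as the centred rolling median over
#' `background_window` bins (edges use shrunken windows), floored at the
#' series mean so that series that are mostly zero between bursts still
#' threshold sensibly.  Candidate bins closer than `min_separation` are
#' merged into one peak whose apex is the maximum of the group.  The
#' detector is invariant under multiplying the series by a positive
#' constant.
#'
#' @param series Numeric vector or [av_series()].
#' @param background_window Rolling-median window in bins (>= 3).
#' @param threshold_factor Multiplicative detection threshold (> 1).
#' @param min_separation Candidates closer than this many bins merge.
#' @return An object of class `av_peaks`: a data frame with columns
#'   `position` (bin index of the apex), `height` (series value there),
#'   `relative_height` (height / background at the apex) and `extent`
#'   (number of candidate bins merged), with the `bin_width` attached as
#'   an attribute.
#' @examples
#' x <- rep(1, 100); x[50] <- 100
#' detect_peaks(x, background_window = 11, threshold_factor = 5)
#' @export
detect_peaks <- function(series, background_window = 21,
                         threshold_factor = 5, min_separation = 3) {
  series <- as_av_series(series)
  v <- series$values
  n <- length(v)
  if (background_window < 3) stop("background_window must be >= 3")
  if (threshold_factor <= 1) stop("threshold_factor must be > 1")
  if (n < background_window) {
    stop("series shorter than background_window")
  }
  empty <- structure(
    data.frame(position = integer(0), height = numeric(0),
               relative_height = numeric(0), extent = integer(0)),
    bin_width = series$bin_width, class = c("av_peaks", "data.frame"))
  mx <- max(v)
  if (mx <= 0) return(empty)
  # floor the background at the series mean: keeps the threshold
  # scale-invariant and meaningful for series whose rolling median is zero
  # between bursts (e.g. new-message counts in the calm regime)
  eps <- mean(v)
  bg <- rolling_median(v, background_window)
  cand <- which(v > threshold_factor * pmax(bg, eps))
  if (length(cand) == 0L) return(empty)
  grp <- cumsum(c(1, diff(cand) >= min_separation))
  pieces <- split(cand, grp)
  position <- integer(length(pieces))
  height <- numeric(length(pieces))
  relh <- numeric(length(pieces))
  extent <- integer(length(pieces))
  for (g in seq_along(pieces)) {
    bins <- pieces[[g]]
    apex <- bins[which.max(v[bins])]
    position[g] <- apex
    height[g] <- v[apex]
    relh[g] <- v[apex] / max(bg[apex], eps)
    extent[g] <- length(bins)
  }
  structure(data.frame(position = position, height = height,
                       relative_height = relh, extent = extent),
            bin_width = series$bin_width,
            class = c("av_peaks", "data.frame"))
}

#' Peak-height and inter-peak-separation samples
#'
#' Extracts the relative peak heights and the successive inter-peak
#' separations (in time units, i.e. position differences times the bin
#' width) from a detected peak set.  An optional minimum-separation filter
#' drops short gaps (the empirical-replication convention of excluding
#' separations of a week or less to avoid over-counting).
#'
#' @param peaks An `av_peaks` object from [detect_peaks()].
#' @param min_gap Optional: keep only separations strictly greater than
#'   this (same time units as `bin_width`); `NULL` (default) keeps all.
#' @return `list(relative_heights, separations)`; `separations` is empty
#'   (not an error) with fewer than two peaks.
#' @export
peak_statistics <- function(peaks, min_gap = NULL) {
  stopifnot(inherits(peaks, "av_peaks"))
  bw <- attr(peaks, "bin_width")
  seps <- if (nrow(peaks) >= 2L) diff(peaks$position) * bw else numeric(0)
  if (!is.null(min_gap)) seps <- seps[seps > min_gap]
  list(relative_heights = peaks$relative_height, separations = seps)
}

# exact one-sample Kolmogorov-Smirnov distance against a cdf function
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

# two-sample KS distance
ks_distance2 <- function(x, y) {
  all_v <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(all_v)
  Fy <- stats::ecdf(y)(all_v)
  max(abs(Fx - Fy))
}

new_dist_fit <- function(family, parameters, n, support = NULL, gof = NULL,
                         degenerate = FALSE) {
  structure(list(family = family, parameters = parameters, n = n,
                 support = support, gof = gof, fitted = TRUE,
                 degenerate = degenerate),
            class = "av_fit")
}

#' Maximum-likelihood lognormal fit
#'
#' Fits `meanlog` and `sdlog` by maximum likelihood (sample mean and
#' root-mean-square deviation of the log samples) and reports the KS
#' distance of the fit.  A sample of identical values yields `sdlog = 0`
#' flagged as degenerate.
#'
#' @param samples Positive numeric vector, length >= 5.
#' @return An `av_fit` with parameters `meanlog`, `sdlog`.
#' @examples
#' set.seed(1)
#' fit_lognormal(rlnorm(500, 1, 0.5))
#' @export
fit_lognormal <- function(samples) {
  if (length(samples) < 5L) stop("need at least 5 samples")
  if (any(samples <= 0)) stop("lognormal fit requires positive samples")
  lx <- log(samples)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  degenerate <- sigma < 1e-12
  gof <- if (degenerate) {
    NULL
  } else {
    list(ks = ks_distance(samples,
                          function(q) stats::plnorm(q, mu, sigma)),
         loglik = sum(stats::dlnorm(samples, mu, sigma, log = TRUE)))
  }
  new_dist_fit("lognormal", c(meanlog = mu, sdlog = sigma),
               length(samples), gof = gof, degenerate = degenerate)
}

# log-likelihood of density proportional to x^g on [xmin, xmax]
plb_loglik <- function(g, n, sum_log, xmin, xmax) {
  g1 <- g + 1
  log_c <- if (abs(g1) < 1e-8) {
    -log(log(xmax / xmin))
  } else {
    log(abs(g1)) - log(abs(xmax^g1 - xmin^g1))
  }
  n * log_c + g * sum_log
}

# cdf of the bounded power law
plb_cdf <- function(q, g, xmin, xmax) {
  g1 <- g + 1
  if (abs(g1) < 1e-8) {
    log(q / xmin) / log(xmax / xmin)
  } else {
    (q^g1 - xmin^g1) / (xmax^g1 - xmin^g1)
  }
}

#' Fit a bounded power law
#'
#' Estimates the exponent of a density proportional to `x^exponent` on the
#' finite support `[xmin, xmax]`.  Bounded support is essential for
#' exponents above -1 (such as the transition-time exponent near -0.75),
#' where the unbounded form is not normalisable.  Two estimators:
#' `"truncated_mle"` maximises the exact truncated likelihood over the
#' exponent; `"logbin_ls"` builds a histogram in logarithmically spaced
#' bins (`bins_per_decade` per decade), converts counts to densities and
#' takes the least-squares slope of log density versus log bin midpoint.
#' If more than half of the bins are empty the bin count is halved with a
#' warning.
#'
#' @param samples Numeric samples, all within `[xmin, xmax]`.
#' @param xmin,xmax Support bounds (defaults: sample range).
#' @param method `"truncated_mle"` (default) or `"logbin_ls"`.
#' @param bins_per_decade Bins per decade for `"logbin_ls"`.
#' @return An `av_fit` with parameters `exponent` and `se`, support, and
#'   the KS distance of the fitted law.
#' @examples
#' set.seed(1)
#' x <- rpowerlaw_bounded(2000, -0.75, 10, 20000)
#' fit_powerlaw_bounded(x, 10, 20000)$parameters["exponent"]
#' @export
fit_powerlaw_bounded <- function(samples, xmin = min(samples),
                                 xmax = max(samples),
                                 method = c("truncated_mle", "logbin_ls"),
                                 bins_per_decade = 15) {
  method <- match.arg(method)
  n <- length(samples)
  if (xmin >= xmax) stop("xmin must be < xmax")
  if (xmin <= 0) stop("xmin must be > 0")
  if (any(samples < xmin) || any(samples > xmax)) {
    stop("all samples must lie within [xmin, xmax]")
  }
  if (method == "truncated_mle") {
    if (n < 2L) stop("need at least 2 samples")
    sum_log <- sum(log(samples))
    opt <- stats::optimize(function(g) plb_loglik(g, n, sum_log, xmin, xmax),
                           interval = c(-10, 5), maximum = TRUE,
                           tol = 1e-9)
    g_hat <- opt$maximum
    # observed information by central second difference
    h <- 1e-4
    d2 <- (plb_loglik(g_hat + h, n, sum_log, xmin, xmax) -
             2 * plb_loglik(g_hat, n, sum_log, xmin, xmax) +
             plb_loglik(g_hat - h, n, sum_log, xmin, xmax)) / h^2
    se <- if (d2 < 0) 1 / sqrt(-d2) else NA_real_
    loglik <- opt$objective
  } else {
    if (n < 20L) stop("logbin_ls needs at least 20 samples")
    bpd <- bins_per_decade
    repeat {
      n_dec <- log10(xmax / xmin)
      nb <- max(3L, ceiling(n_dec * bpd))
      breaks <- 10^seq(log10(xmin), log10(xmax), length.out = nb + 1L)
      breaks[nb + 1L] <- xmax * (1 + 1e-12)
      counts <- tabulate(findInterval(samples, breaks,
                                      rightmost.closed = TRUE), nbins = nb)
      if (mean(counts == 0) <= 0.5 || bpd <= 2) break
      bpd <- max(2, floor(bpd / 2))
      warning("many empty log bins; reducing to ", bpd,
              " bins per decade", call. = FALSE)
    }
    keep <- counts > 0
    width <- diff(breaks)
    dens <- counts[keep] / (width[keep] * n)
    mid <- sqrt(breaks[-(nb + 1L)] * breaks[-1L])[keep]
    if (sum(keep) < 3L) stop("too few occupied bins for a slope fit")
    lf <- stats::lm(log(dens) ~ log(mid))
    g_hat <- unname(stats::coef(lf)[2])
    se <- unname(summary(lf)$coefficients[2, 2])
    loglik <- NA_real_
  }
  gof <- list(ks = ks_distance(samples,
                               function(q) plb_cdf(q, g_hat, xmin, xmax)),
              loglik = loglik)
  new_dist_fit("powerlaw_bounded", c(exponent = g_hat, se = se), n,
               support = c(xmin = xmin, xmax = xmax), gof = gof)
}

#' Sample from a bounded power law
#'
#' Inverse-CDF sampling from a density proportional to `x^exponent` on
#' `[xmin, xmax]` (any real exponent; the support makes it normalisable).
#'
#' @param n Number of draws.
#' @param exponent Power-law exponent (e.g. -0.75).
#' @param xmin,xmax Support bounds, `0 < xmin < xmax`.
#' @return Numeric vector of `n` samples.
#' @export
rpowerlaw_bounded <- function(n, exponent, xmin, xmax) {
  stopifnot(xmin > 0, xmin < xmax)
  u <- stats::runif(n)
  g1 <- exponent + 1
  if (abs(g1) < 1e-12) {
    exp(log(xmin) + u * log(xmax / xmin))
  } else {
    (xmin^g1 + u * (xmax^g1 - xmin^g1))^(1 / g1)
  }
}

#' Maximum-likelihood log-Cauchy fit
#'
#' Fits location and scale of a Cauchy distribution to the log samples by
#' maximum likelihood (numerical optimisation, started at the median and
#' half-IQR of the logs), the heavy-tailed family describing slowly
#' decaying discussion-thread activity.
#'
#' @param samples Positive numeric vector, length >= 20.
#' @return An `av_fit` with parameters `location` and `scale` (of the
#'   Cauchy on the log scale).
#' @examples
#' set.seed(1)
#' fit_logcauchy(exp(rcauchy(500, 2, 0.5)))
#' @export
fit_logcauchy <- function(samples) {
  if (length(samples) < 20L) stop("need at least 20 samples")
  if (any(!is.finite(samples)) || any(samples <= 0)) {
    stop("log-Cauchy fit requires finite positive samples")
  }
  lx <- log(samples)
  iqr2 <- stats::IQR(lx) / 2
  if (iqr2 < 1e-12) {
    return(new_dist_fit("logcauchy",
                        c(location = stats::median(lx), scale = 0),
                        length(samples), degenerate = TRUE))
  }
  fd <- MASS::fitdistr(lx, "cauchy",
                       start = list(location = stats::median(lx),
                                    scale = iqr2),
                       lower = c(-Inf, 1e-12))
  loc <- unname(fd$estimate["location"])
  sc <- unname(fd$estimate["scale"])
  gof <- list(ks = ks_distance(samples,
                               function(q) stats::pcauchy(log(q), loc, sc)),
              loglik = fd$loglik)
  new_dist_fit("logcauchy", c(location = loc, scale = sc), length(samples),
               gof = gof)
}

#' Match simulated to reference separations by time rescaling
#'
#' Finds the factor from `factor_grid` that minimises the two-sample KS
#' distance between `factor * sim_separations` and
#' `reference_separations` — the conversion between simulation ticks and
#' real-world time units.
#'
#' @param sim_separations,reference_separations Non-empty numeric vectors.
#' @param factor_grid Candidate rescaling factors.
#' @return `list(factor, ks, factor_grid, ks_values)`; ties resolve to the
#'   first grid entry.
#' @examples
#' set.seed(1)
#' s <- rlnorm(200, 4, 0.5)
#' rescale_time_match(s, 4.5 * s, seq(1, 10, by = 0.5))$factor
#' @export
rescale_time_match <- function(sim_separations, reference_separations,
                               factor_grid) {
  stopifnot(length(sim_separations) > 0, length(reference_separations) > 0,
            length(factor_grid) > 0)
  ks_values <- vapply(factor_grid, function(f) {
    ks_distance2(f * sim_separations, reference_separations)
  }, numeric(1))
  best <- which.min(ks_values)
  list(factor = factor_grid[best], ks = ks_values[best],
       factor_grid = factor_grid, ks_values = ks_values)
}
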