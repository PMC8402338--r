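#' Generate a synthetic bursty activity series with ground truth
#'
#' Builds a series that mirrors the statistical structure of bursty
#' vaccine-debate activity: a low Poisson background with isolated spikes
#' whose heights are lognormal and whose successive gaps are lognormal.
#' Returns the ground-truth peak list alongside the series, so peak
#' detectors and distribution fitters can be tested end-to-end without any
#' empirical corpus.  Consumes the current R random stream (`set.seed()`
#' first for reproducibility).
#'
#' @param n_peaks Number of spikes to place.
#' @param height_meanlog,height_sdlog Lognormal parameters of spike
#'   heights.
#' @param gap_meanlog,gap_sdlog Lognormal parameters of the inter-spike
#'   gaps (in bins).
#' @param background_rate Poisson rate of the background per bin (0 gives
#'   an exactly-zero background).
#' @param length Series length in bins.
#' @param bin_width Time units per bin.
#' @return `list(series, peaks)`: an [av_series()] and a data frame of
#'   true `position` and `height`.  Peaks falling beyond `length` are
#'   truncated with a warning.
#' @examples
#' set.seed(1)
#' fx <- generate_synthetic_bursts(n_peaks = 5, background_rate = 0.5)
#' nrow(fx$peaks)
#' @export
generate_synthetic_bursts <- function(n_peaks,
                                      height_meanlog = 4,
                                      height_sdlog = 0.6,
                                      gap_meanlog = 4,
                                      gap_sdlog = 0.5,
                                      background_rate = 1,
                                      length = 2000,
                                      bin_width = 1) {
  stopifnot(n_peaks >= 0, height_sdlog >= 0, gap_sdlog >= 0,
            background_rate >= 0, length >= 1)
  gaps <- stats::rlnorm(n_peaks, gap_meanlog, gap_sdlog)
  positions <- round(cumsum(pmax(gaps, 1)))
  # enforce strictly increasing integer positions
  if (n_peaks > 1) {
    for (i in 2:n_peaks) {
      if (positions[i] <= positions[i - 1]) {
        positions[i] <- positions[i - 1] + 1
      }
    }
  }
  heights <- stats::rlnorm(n_peaks, height_meanlog, height_sdlog)
  keep <- positions >= 1 & positions <= length
  if (any(!keep)) {
    warning(sum(!keep), " peak(s) fell beyond the series length; truncated",
            call. = FALSE)
  }
  positions <- as.integer(positions[keep])
  heights <- heights[keep]
  values <- if (background_rate > 0) {
    as.numeric(stats::rpois(length, background_rate))
  } else {
    numeric(length)
  }
  values[positions] <- values[positions] + heights
  list(series = av_series(values, bin_width = bin_width,
                          label = "synthetic bursts"),
       peaks = data.frame(position = positions, height = heights))
}
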