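# Burst statistics applied to simulation output: the glue between the
# engine's per-tick metrics and the generic peak/fit machinery.

#' Aggregate a series into coarser bins
#'
#' Sums consecutive groups of `width` bins (a trailing incomplete group is
#' dropped), the discrete analogue of regrouping daily counts into weekly
#' ones.
#'
#' @param series Numeric vector or [av_series()].
#' @param width Number of original bins per aggregated bin.
#' @return An `av_series` whose `bin_width` is scaled by `width`.
#' @examples
#' bin_series(1:10, 5)   # values 15, 40
#' @export
bin_series <- function(series, width) {
  series <- as_av_series(series)
  width <- as.integer(width)
  if (width < 1) stop("width must be >= 1")
  v <- series$values
  n <- floor(length(v) / width)
  if (n < 1) stop("series shorter than one aggregated bin")
  out <- colSums(matrix(v[seq_len(n * width)], nrow = width))
  av_series(out, bin_width = series$bin_width * width, label = series$label)
}

#' Burst statistics of a simulation's new-message activity
#'
#' Extracts the per-tick count of newly written activist messages
#' (initiator messages excluded), restricts it to the fluctuating regime —
#' everything before the antivaxxer fraction first exceeds `frac_cutoff`,
#' so a final run-away transition does not drown the burst background —
#' aggregates it into bins of `bin_width` ticks and runs [detect_peaks()]
#' plus a lognormal fit of the relative peak heights with its KS
#' goodness-of-fit p-value.
#'
#' @param sim An `av_simulation` from [run_simulation()].
#' @param bin_width Ticks per aggregated bin.
#' @param frac_cutoff Antivaxxer fraction marking the end of the
#'   fluctuating regime.
#' @param background_window,threshold_factor,min_separation Passed to
#'   [detect_peaks()].
#' @return List with `n_peaks`, `peaks` (an `av_peaks`), `fit` (an
#'   `av_fit`, `NULL` with fewer than 5 peaks), `ks_p` (`NA` when no fit),
#'   `series` (the binned `av_series`) and `ticks_used`.
#' @export
analyze_message_bursts <- function(sim, bin_width = 50, frac_cutoff = 0.25,
                                   background_window = 21,
                                   threshold_factor = 5,
                                   min_separation = 3) {
  stopifnot(inherits(sim, "av_simulation"))
  m <- sim$metrics
  frac <- m$n_antivax / sim$params$n_patients
  cut <- which(frac > frac_cutoff)
  t_end <- if (length(cut)) cut[1] - 1L else nrow(m)
  v <- m$new_messages[seq_len(t_end)]
  empty <- list(n_peaks = 0L, peaks = NULL, fit = NULL, ks_p = NA_real_,
                series = NULL, ticks_used = t_end)
  if (t_end < bin_width * background_window) return(empty)
  series <- bin_series(v, bin_width)
  peaks <- detect_peaks(series, background_window = background_window,
                        threshold_factor = threshold_factor,
                        min_separation = min_separation)
  fit <- NULL
  ks_p <- NA_real_
  if (nrow(peaks) >= 5L) {
    fit <- fit_lognormal(peaks$relative_height)
    if (!fit$degenerate) {
      ks_p <- suppressWarnings(stats::ks.test(
        peaks$relative_height, "plnorm",
        fit$parameters[["meanlog"]], fit$parameters[["sdlog"]]))$p.value
    }
  }
  list(n_peaks = nrow(peaks), peaks = peaks, fit = fit, ks_p = ks_p,
       series = series, ticks_used = t_end)
}
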