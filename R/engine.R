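#' Detect the anti-vaccination success transition in a run
#'
#' The catastrophic "AV success" state is declared when the antivaxxer
#' fraction NAV/NP stays at or above `success_threshold` for
#' `confirm_ticks` consecutive ticks.  `transition_time` is the first tick
#' of that confirmed window.  `transition_duration` measures the speed of
#' the final ascent: the number of ticks from the last time the fraction
#' was at or below `base_threshold` to the start of the window (an
#' instantaneous jump gives duration 0).
#'
#' @param nav_frac Numeric vector of NAV/NP per tick (tick 1, 2, ...).
#' @param confirm_ticks Consecutive ticks required to confirm success
#'   (default: one patient lifetime, 90).
#' @param success_threshold,base_threshold Fractions defining the confirmed
#'   state and the pre-transition baseline (defaults 0.95 and 0.5).
#' @return `list(av_success, transition_time, transition_duration)`;
#'   the last two are `NA` when no success occurred.
#' @examples
#' f <- c(rep(0, 99), rep(1, 120))
#' detect_av_success(f, confirm_ticks = 90)  # success at tick 100, duration 0
#' @export
detect_av_success <- function(nav_frac, confirm_ticks = 90,
                              success_threshold = 0.95,
                              base_threshold = 0.5) {
  stopifnot(length(nav_frac) >= 1, confirm_ticks >= 1,
            base_threshold < success_threshold)
  above <- nav_frac >= success_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= confirm_ticks)
  if (length(hit) == 0L) {
    return(list(av_success = FALSE, transition_time = NA_integer_,
                transition_duration = NA_integer_))
  }
  tt <- starts[hit[1]]
  below <- which(nav_frac[seq_len(tt)] <= base_threshold)
  t50 <- if (length(below)) max(below) + 1L else 1L
  list(av_success = TRUE, transition_time = as.integer(tt),
       transition_duration = as.integer(tt - t50))
}

#' Run one simulation
#'
#' Initialises the populations from `seed` and advances the four-process
#' tick loop up to `max_ticks`, recording per-tick metrics and detecting
#' the AV-success transition.  Deterministic: identical `(params, seed)`
#' yield identical results, for either engine.  The default compiled
#' engine and the naive `"reference"` engine consume the R random stream
#' in the same order and produce bit-identical output (a tested
#' invariant); the reference engine is orders of magnitude slower and
#' intended for small instances.
#'
#' @param params An [model_params()] record.
#' @param seed Integer seed for R's RNG.
#' @param engine `"cpp"` (default) or `"reference"`.
#' @param early_stop Stop once success is confirmed (the transition is
#'   absorbing in practice); metrics up to the stop are kept.
#' @param success_threshold,base_threshold,confirm_ticks Success-criterion
#'   knobs, see [detect_av_success()]; `confirm_ticks` defaults to
#'   `params$patient_lifetime`.
#' @return An object of class `av_simulation`: list with `params`, `seed`,
#'   `engine`, `metrics` (data frame, one row per tick), `av_success`,
#'   `transition_time`, `transition_duration`, `ticks_run`, and the final
#'   `state`.
#' @examples
#' p <- model_params(n_patients = 50, n_doctors = 5, max_ticks = 200)
#' r <- run_simulation(p, seed = 1)
#' head(r$metrics)
#' @export
run_simulation <- function(params, seed, engine = c("cpp", "reference"),
                           early_stop = TRUE,
                           success_threshold = 0.95, base_threshold = 0.5,
                           confirm_ticks = NULL) {
  validate_params(params)
  engine <- match.arg(engine)
  if (is.null(confirm_ticks)) {
    confirm_ticks <- as.integer(params$patient_lifetime)
  }
  set.seed(as.integer(seed))
  state <- engine_init_state(params)
  if (engine == "cpp") {
    res <- run_engine_cpp(params, state$p_op, state$p_age,
                          state$doctors$opinion, state$doctors$uncommitted,
                          params$max_ticks, early_stop, success_threshold,
                          as.integer(confirm_ticks), 0L)
    metrics <- as.data.frame(res$metrics)
    names(metrics) <- c("tick", "new_messages", "new_messages_total",
                        "active_messages", "n_antivax", "n_activists",
                        "n_uncommitted_doctors", "mean_opinion")
    final_state <- list(tick = res$ticks_run, p_op = res$p_op,
                        p_age = res$p_age,
                        doctors = list(opinion = res$d_op,
                                       uncommitted = res$d_unc),
                        msg_op = res$msg_op, msg_age = res$msg_age,
                        msg_init = res$msg_init)
  } else {
    res <- run_engine_reference(state, params, params$max_ticks, early_stop,
                                success_threshold, confirm_ticks)
    metrics <- res$metrics
    rownames(metrics) <- NULL
    final_state <- res$state
  }
  for (col in c("tick", "new_messages", "new_messages_total",
                "active_messages", "n_antivax", "n_activists",
                "n_uncommitted_doctors")) {
    metrics[[col]] <- as.integer(metrics[[col]])
  }
  det <- detect_av_success(metrics$n_antivax / params$n_patients,
                           confirm_ticks, success_threshold, base_threshold)
  structure(list(params = params, seed = as.integer(seed), engine = engine,
                 metrics = metrics, av_success = det$av_success,
                 transition_time = det$transition_time,
                 transition_duration = det$transition_duration,
                 ticks_run = nrow(metrics), state = final_state),
            class = "av_simulation")
}

#' @export
print.av_simulation <- function(x, ...) {
  cat(sprintf("<av_simulation> seed %d, %d ticks (%s engine)\n",
              x$seed, x$ticks_run, x$engine))
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("  final: NAV = %d/%d, activists = %d, active messages = %d\n",
              last$n_antivax, x$params$n_patients, last$n_activists,
              last$active_messages))
  if (x$av_success) {
    cat(sprintf("  AV success at tick %d (ascent duration %d ticks)\n",
                x$transition_time, x$transition_duration))
  } else {
    cat("  no AV-success transition\n")
  }
  invisible(x)
}
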