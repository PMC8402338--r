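#' Specify an ensemble of simulation runs
#'
#' Describes a deterministic ensemble over a grid of parameter overrides
#' (typically the activism threshold AT and the writing probability PW)
#' with `n_reps` replicates per grid cell.  Replicate `j` (0-based) of cell
#' `i` (0-based) runs with seed `base_seed + i * n_reps + j`, so the whole
#' ensemble is reproducible from `base_seed` and independent of execution
#' order.
#'
#' @param base_params An [model_params()] record.
#' @param grid A data frame, one row per cell, whose columns are parameter
#'   names to override (e.g. `activism_threshold`, `writing_probability`).
#' @param n_reps Replicates per cell (>= 1).
#' @param base_seed Integer base seed.
#' @return An object of class `av_ensemble_spec`.
#' @examples
#' spec <- ensemble_spec(model_params(n_patients = 100),
#'                       grid = data.frame(writing_probability = c(0.2, 0.6)),
#'                       n_reps = 3, base_seed = 42)
#' @export
ensemble_spec <- function(base_params, grid, n_reps, base_seed) {
  validate_params(base_params)
  if (!is.data.frame(grid) || nrow(grid) < 1L) {
    stop("`grid` must be a data frame with at least one row")
  }
  unknown <- setdiff(names(grid), names(base_params))
  if (length(unknown)) {
    stop("grid columns are not model parameters: ",
         paste(unknown, collapse = ", "))
  }
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("`n_reps` must be >= 1")
  structure(list(base_params = base_params, grid = grid, n_reps = n_reps,
                 base_seed = as.integer(base_seed)),
            class = "av_ensemble_spec")
}

#' Run an ensemble over a parameter grid
#'
#' Executes every replicate of every cell of an [ensemble_spec()] with the
#' documented seeding scheme and collects, per cell, the AV-success count,
#' ratio and the transition times of the successful runs.
#'
#' @param spec An `av_ensemble_spec`.
#' @param ... Passed on to [run_simulation()] (e.g. `success_threshold`).
#' @param progress Emit a one-line progress note per cell on stderr.
#' @return An object of class `av_ensemble`: list with `cells` (the grid
#'   plus `success_count`, `n_reps`, `success_ratio` columns),
#'   `transition_times` (list of numeric vectors, one per cell),
#'   `transition_durations` (same shape), `seeds` (list of the seeds
#'   used), and the `spec`.
#' @export
run_ensemble <- function(spec, ..., progress = FALSE) {
  stopifnot(inherits(spec, "av_ensemble_spec"))
  ncell <- nrow(spec$grid)
  cells <- spec$grid
  cells$success_count <- 0L
  cells$n_reps <- spec$n_reps
  cells$success_ratio <- 0
  tt <- vector("list", ncell)
  td <- vector("list", ncell)
  seeds <- vector("list", ncell)
  for (i in seq_len(ncell)) {
    overrides <- as.list(spec$grid[i, , drop = FALSE])
    p <- tryCatch(do.call(update_params, c(list(spec$base_params), overrides)),
                  error = function(e) {
                    stop(sprintf("cell %d: %s", i, conditionMessage(e)),
                         call. = FALSE)
                  })
    cell_seeds <- spec$base_seed + (i - 1L) * spec$n_reps +
      seq_len(spec$n_reps) - 1L
    times <- numeric(0)
    durs <- numeric(0)
    for (s in cell_seeds) {
      r <- run_simulation(p, seed = s, ...)
      if (r$av_success) {
        times <- c(times, r$transition_time)
        durs <- c(durs, r$transition_duration)
      }
    }
    cells$success_count[i] <- length(times)
    cells$success_ratio[i] <- length(times) / spec$n_reps
    tt[[i]] <- times
    td[[i]] <- durs
    seeds[[i]] <- cell_seeds
    if (progress) {
      message(sprintf("cell %d/%d done: success %d/%d", i, ncell,
                      length(times), spec$n_reps))
    }
  }
  structure(list(cells = cells, transition_times = tt,
                 transition_durations = td, seeds = seeds, spec = spec),
            class = "av_ensemble")
}

#' @export
print.av_ensemble <- function(x, ...) {
  cat(sprintf("<av_ensemble> %d cells x %d reps (base seed %d)\n",
              nrow(x$cells), x$spec$n_reps, x$spec$base_seed))
  print(x$cells)
  invisible(x)
}

#' Fit a sigmoid to the success-ratio curve
#'
#' Least-squares fit of the AV-success ratio as a function of the writing
#' probability PW, with either a logistic
#' `L / (1 + exp(-s * (PW - x0)))` or a Gompertz
#' `a * exp(-b * exp(-c * PW))` family; the amplitude (`L` or `a`) is
#' capped at 1.  The reported `location` is the PW at half of the fitted
#' amplitude (for the logistic this is `x0`).
#'
#' @param pw Numeric vector of writing probabilities.
#' @param ratio Success ratios in \[0, 1\], same length.
#' @param family `"logistic"` or `"gompertz"`.
#' @return An object of class `av_fit` with fields `family`, `parameters`
#'   (named vector, including `location`), `n`, `gof` (residual norm) and
#'   `fitted` (`FALSE` with a `reason` for degenerate input — e.g. all
#'   ratios equal — instead of an error).
#' @examples
#' pw <- seq(0.1, 0.9, by = 0.1)
#' r <- 1 / (1 + exp(-20 * (pw - 0.5)))
#' fit_success_sigmoid(pw, r)$parameters["location"]
#' @export
fit_success_sigmoid <- function(pw, ratio, family = c("logistic", "gompertz")) {
  family <- match.arg(family)
  stopifnot(length(pw) == length(ratio), all(is.finite(pw)),
            all(is.finite(ratio)))
  if (length(pw) < 4L) {
    stop("need at least 4 points to fit a sigmoid")
  }
  no_fit <- function(reason) {
    structure(list(family = family, parameters = NULL, n = length(pw),
                   gof = NULL, fitted = FALSE, reason = reason),
              class = "av_fit")
  }
  if (diff(range(ratio)) < 1e-12) {
    return(no_fit("degenerate input: all success ratios equal"))
  }
  df <- data.frame(pw = pw, ratio = ratio)
  # crude location start: PW where the ratio first crosses half its range
  half <- min(ratio) + diff(range(ratio)) / 2
  x0_start <- pw[which.min(abs(ratio - half))]
  fit <- tryCatch({
    if (family == "logistic") {
      minpack.lm::nlsLM(ratio ~ L / (1 + exp(-s * (pw - x0))), data = df,
                        start = list(L = min(1, max(ratio)), s = 20,
                                     x0 = x0_start),
                        lower = c(L = 1e-6, s = 1e-3, x0 = -10),
                        upper = c(L = 1, s = 1e4, x0 = 10),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(ratio ~ a * exp(-b * exp(-c * pw)), data = df,
                        start = list(a = min(1, max(ratio)), b = 10,
                                     c = 10 / max(x0_start, 1e-3)),
                        lower = c(a = 1e-6, b = 1e-6, c = 1e-6),
                        upper = c(a = 1, b = 1e6, c = 1e6),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(no_fit("nonlinear least squares did not converge"))
  cf <- stats::coef(fit)
  location <- if (family == "logistic") {
    unname(cf["x0"])
  } else {
    # PW at half the fitted amplitude: a/2 = a exp(-b exp(-c x))
    unname(log(cf["b"] / log(2)) / cf["c"])
  }
  structure(list(family = family,
                 parameters = c(cf, location = location),
                 n = length(pw),
                 gof = list(residual_norm =
                              sqrt(sum(stats::resid(fit)^2))),
                 fitted = TRUE),
            class = "av_fit")
}

#' @export
print.av_fit <- function(x, ...) {
  cat(sprintf("<av_fit> family = %s, n = %d\n", x$family, x$n))
  if (!isTRUE(x$fitted)) {
    cat("  no fit:", x$reason, "\n")
    return(invisible(x))
  }
  cat("  parameters:\n")
  for (nm in names(x$parameters)) {
    cat(sprintf("    %-12s %.6g\n", nm, x$parameters[[nm]]))
  }
  if (!is.null(x$gof)) {
    for (nm in names(x$gof)) {
      cat(sprintf("  gof %-10s %.6g\n", nm, x$gof[[nm]]))
    }
  }
  invisible(x)
}
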