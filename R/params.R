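#' Model parameters for the anti-vaccination opinion dynamics simulation
#'
#' Builds and validates the full parameter record of the agent-based model.
#' The society consists of `n_patients` patients whose opinions live on the
#' closed interval `opinion_bounds` (+2 strong support of vaccination, -2
#' strong opposition, by default), `n_doctors` doctors, a handful of
#' fixed-opinion `n_initiators` seeding the anti-vaccination message stream,
#' and an infosphere pool of messages that clone their author's opinion at
#' creation and expire after `message_lifetime` ticks.
#'
#' A patient with opinion below `vaccination_threshold` (VT) refuses
#' vaccination ("antivaxxer"); below `activism_threshold` (AT) it becomes an
#' "activist" that writes messages and filters incoming information most
#' aggressively.  Opinion updates are convex combinations with acceptance
#' rate `alpha` discounted by the asymmetric filtering factor (see
#' [filtering_factor()]).  The fraction of "uncommitted" doctors tracks the
#' antivaxxer ratio as `round(n_doctors * k * NAV / NP)` with
#' `k = doctor_hesitancy_factor`.
#'
#' @param n_patients Number of patients (NP), constant over a run.
#' @param n_doctors Number of doctors (ND).
#' @param n_initiators Number of fixed-opinion initiators (NI); may be 0.
#'   The default of a single initiator keeps the standing initiator message
#'   stock small enough for a metastable pro-vaccination background.
#' @param initiator_opinion Fixed opinion of every initiator; must lie below
#'   `activism_threshold`.  The default (-1.83) sits just below the deeper
#'   of the two activism thresholds studied, so that a single initiator
#'   message cannot convert a patient far above the threshold — activist
#'   genesis then depends strongly on the threshold, which is what shifts
#'   the phase boundary between thresholds (see the methods vignette).
#' @param alpha Acceptance rate of the opinion update, in (0, 1].
#' @param opinion_center,opinion_sd Center (OC) and standard deviation (OSD)
#'   of the truncated normal from which fresh patient opinions are drawn.
#' @param opinion_bounds Length-2 numeric, closed opinion interval; must be
#'   symmetric about 0 (the filtering formula uses its magnitude).
#' @param vaccination_threshold Opinion below which a patient refuses
#'   vaccination (VT).
#' @param activism_threshold Opinion below which a patient becomes an
#'   activist (AT); must satisfy `lower <= AT < VT <= 0`.
#' @param filtering_threshold Absolute opinion above which non-activists
#'   start filtering opposing sources (FT), in (0, upper bound).
#' @param writing_probability Probability PW that each of the (up to)
#'   `max_messages_per_author_per_tick` writing attempts of an initiator or
#'   activist succeeds in a tick.
#' @param doctor_visit_ratio Per-tick probability PVD that a patient visits
#'   a random doctor (personal contact plus exposure to official
#'   pro-vaccination communication).  The default of 1 — a guaranteed
#'   per-tick contact — is the baseline institutional pressure needed to
#'   hold the metastable pro-vaccination state against the unfiltered
#'   emotional appeal of anti-vaccination messages.
#' @param doctor_hesitancy_factor Proportionality factor k in (0, 1) tying
#'   the uncommitted-doctor ratio to the antivaxxer ratio.
#' @param patient_lifetime,message_lifetime Maximum age (ticks) of patients
#'   and messages.  Patients reaching it are replaced by fresh agents;
#'   messages are simply removed.
#' @param activist_aging_factor Ageing speed of activists relative to
#'   ordinary patients (default 0.5: activists stay engaged twice as long).
#' @param max_messages_per_author_per_tick Writing attempts per author per
#'   tick (each an independent Bernoulli(PW) trial).
#' @param committed_doctor_opinion_range,uncommitted_doctor_opinion_range
#'   Uniform ranges from which committed / uncommitted doctor opinions are
#'   drawn.
#' @param message_cap Optional cap on the message-pool size (censoring
#'   intervention); `NULL` (default) disables it.
#' @param max_ticks Maximum number of simulation ticks.
#'
#' @return An object of class `av_params`: a validated named list with the
#'   fields above.
#' @examples
#' p <- model_params()                      # paper defaults
#' p2 <- model_params(writing_probability = 0.7, activism_threshold = -1.8)
#' @export
model_params <- function(n_patients = 2000L,
                         n_doctors = 100L,
                         n_initiators = 1L,
                         initiator_opinion = -1.83,
                         alpha = 0.66,
                         opinion_center = 0,
                         opinion_sd = 0.5,
                         opinion_bounds = c(-2, 2),
                         vaccination_threshold = -1,
                         activism_threshold = -1.8,
                         filtering_threshold = 1,
                         writing_probability = 0.45,
                         doctor_visit_ratio = 1,
                         doctor_hesitancy_factor = 0.5,
                         patient_lifetime = 90,
                         message_lifetime = 90,
                         activist_aging_factor = 0.5,
                         max_messages_per_author_per_tick = 5L,
                         committed_doctor_opinion_range = c(1, 2),
                         uncommitted_doctor_opinion_range = c(-0.25, 0),
                         message_cap = NULL,
                         max_ticks = 20000L) {
  p <- list(
    n_patients = as.integer(n_patients),
    n_doctors = as.integer(n_doctors),
    n_initiators = as.integer(n_initiators),
    initiator_opinion = as.numeric(initiator_opinion),
    alpha = as.numeric(alpha),
    opinion_center = as.numeric(opinion_center),
    opinion_sd = as.numeric(opinion_sd),
    opinion_bounds = as.numeric(opinion_bounds),
    vaccination_threshold = as.numeric(vaccination_threshold),
    activism_threshold = as.numeric(activism_threshold),
    filtering_threshold = as.numeric(filtering_threshold),
    writing_probability = as.numeric(writing_probability),
    doctor_visit_ratio = as.numeric(doctor_visit_ratio),
    doctor_hesitancy_factor = as.numeric(doctor_hesitancy_factor),
    patient_lifetime = as.numeric(patient_lifetime),
    message_lifetime = as.numeric(message_lifetime),
    activist_aging_factor = as.numeric(activist_aging_factor),
    max_messages_per_author_per_tick =
      as.integer(max_messages_per_author_per_tick),
    committed_doctor_opinion_range = as.numeric(committed_doctor_opinion_range),
    uncommitted_doctor_opinion_range =
      as.numeric(uncommitted_doctor_opinion_range),
    message_cap = if (is.null(message_cap)) NULL else as.integer(message_cap),
    max_ticks = as.integer(max_ticks)
  )
  class(p) <- "av_params"
  validate_params(p)
  p
}

#' Validate a parameter record
#'
#' Checks every invariant of the model parameter set and stops with a
#' message naming the offending field on the first violation.  Called by
#' [model_params()]; exported so that externally constructed or modified
#' records can be re-checked.
#'
#' @param p An `av_params` object (or bare named list with the same fields).
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(field, "must be a single finite number")
    }
    v
  }
  np <- num1("n_patients"); nd <- num1("n_doctors"); ni <- num1("n_initiators")
  if (np < 1) fail("n_patients", "must be >= 1")
  if (nd < 1) fail("n_doctors", "must be >= 1")
  if (ni < 0) fail("n_initiators", "must be >= 0")

  b <- p$opinion_bounds
  if (!is.numeric(b) || length(b) != 2L || b[1] >= b[2]) {
    fail("opinion_bounds", "must be an increasing length-2 numeric")
  }
  if (!isTRUE(all.equal(b[1], -b[2]))) {
    fail("opinion_bounds", "must be symmetric about 0")
  }

  alpha <- num1("alpha")
  if (alpha <= 0 || alpha > 1) fail("alpha", "must lie in (0, 1]")
  pw <- num1("writing_probability")
  if (pw < 0 || pw > 1) fail("writing_probability", "must lie in [0, 1]")
  pvd <- num1("doctor_visit_ratio")
  if (pvd < 0 || pvd > 1) fail("doctor_visit_ratio", "must lie in [0, 1]")
  k <- num1("doctor_hesitancy_factor")
  if (k <= 0 || k >= 1) fail("doctor_hesitancy_factor", "must lie in (0, 1)")

  osd <- num1("opinion_sd")
  if (osd < 0) fail("opinion_sd", "must be >= 0")
  oc <- num1("opinion_center")
  if (oc < b[1] || oc > b[2]) {
    fail("opinion_center", "must lie within opinion_bounds")
  }

  at <- num1("activism_threshold")
  vt <- num1("vaccination_threshold")
  ft <- num1("filtering_threshold")
  if (!(b[1] <= at)) fail("activism_threshold", "must be >= lower opinion bound")
  if (!(at < vt)) fail("activism_threshold", "must be < vaccination_threshold")
  if (!(vt <= 0)) fail("vaccination_threshold", "must be <= 0")
  if (!(ft > 0)) fail("filtering_threshold", "must be > 0")
  if (!(ft < b[2])) {
    fail("filtering_threshold",
         "must be strictly below the upper opinion bound")
  }

  io <- num1("initiator_opinion")
  if (io < b[1] || io > b[2]) {
    fail("initiator_opinion", "must lie within opinion_bounds")
  }
  if (!(io < at)) fail("initiator_opinion", "must be < activism_threshold")

  pl <- num1("patient_lifetime")
  if (pl <= 0) fail("patient_lifetime", "must be > 0")
  ml <- num1("message_lifetime")
  if (ml <= 0) fail("message_lifetime", "must be > 0")
  af <- num1("activist_aging_factor")
  if (af <= 0 || af > 1) fail("activist_aging_factor", "must lie in (0, 1]")
  mm <- num1("max_messages_per_author_per_tick")
  if (mm < 1) fail("max_messages_per_author_per_tick", "must be >= 1")
  mt <- num1("max_ticks")
  if (mt < 1) fail("max_ticks", "must be >= 1")

  cr <- p$committed_doctor_opinion_range
  ur <- p$uncommitted_doctor_opinion_range
  if (!is.numeric(cr) || length(cr) != 2L || cr[1] > cr[2]) {
    fail("committed_doctor_opinion_range", "must be a length-2 interval")
  }
  if (!is.numeric(ur) || length(ur) != 2L || ur[1] > ur[2]) {
    fail("uncommitted_doctor_opinion_range", "must be a length-2 interval")
  }
  if (cr[1] < b[1] || cr[2] > b[2]) {
    fail("committed_doctor_opinion_range", "must lie within opinion_bounds")
  }
  if (ur[1] < b[1] || ur[2] > b[2]) {
    fail("uncommitted_doctor_opinion_range", "must lie within opinion_bounds")
  }

  if (!is.null(p$message_cap)) {
    mc <- p$message_cap
    if (!is.numeric(mc) || length(mc) != 1L || mc < 1) {
      fail("message_cap", "must be a single count >= 1 (or NULL)")
    }
  }
  invisible(p)
}

#' @export
print.av_params <- function(x, ...) {
  cat("<av_params> agent-based anti-vaccination opinion model\n")
  cat(sprintf("  populations: NP = %d patients, ND = %d doctors, NI = %d initiators\n",
              x$n_patients, x$n_doctors, x$n_initiators))
  cat(sprintf("  opinion scale [%g, %g], initial N(%g, %g) truncated\n",
              x$opinion_bounds[1], x$opinion_bounds[2],
              x$opinion_center, x$opinion_sd))
  cat(sprintf("  thresholds: VT = %g, AT = %g, FT = %g\n",
              x$vaccination_threshold, x$activism_threshold,
              x$filtering_threshold))
  cat(sprintf("  rates: alpha = %g, PW = %g, PVD = %g, k = %g\n",
              x$alpha, x$writing_probability, x$doctor_visit_ratio,
              x$doctor_hesitancy_factor))
  cat(sprintf("  lifetimes: patients %g (activists x%g), messages %g; max %d ticks\n",
              x$patient_lifetime, x$activist_aging_factor,
              x$message_lifetime, x$max_ticks))
  if (!is.null(x$message_cap)) {
    cat(sprintf("  intervention: message pool capped at %d\n", x$message_cap))
  }
  invisible(x)
}

#' Modify a parameter record
#'
#' Returns a copy of `p` with the named fields replaced and all invariants
#' re-validated.  Convenience for sweep grids and tests.
#'
#' @param p An `av_params` object.
#' @param ... Named fields to replace.
#' @return A validated `av_params` object.
#' @examples
#' p <- update_params(model_params(), writing_probability = 0.7)
#' @export
update_params <- function(p, ...) {
  mods <- list(...)
  if (length(mods) == 0L) return(p)
  nm <- names(mods)
  if (is.null(nm) || any(nm == "")) stop("all modifications must be named")
  unknown <- setdiff(nm, names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  for (f in nm) p[[f]] <- mods[[f]]
  # retain integer storage where the constructor uses it
  int_fields <- c("n_patients", "n_doctors", "n_initiators",
                  "max_messages_per_author_per_tick", "max_ticks")
  for (f in intersect(nm, int_fields)) p[[f]] <- as.integer(p[[f]])
  if ("message_cap" %in% nm && !is.null(p$message_cap)) {
    p$message_cap <- as.integer(p$message_cap)
  }
  validate_params(p)
  p
}
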