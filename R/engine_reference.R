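# Naive per-agent reference engine.  This file *defines* the tick semantics
# and the exact order in which the model consumes the R random stream; the
# compiled engine (src/engine.cpp) mirrors both and must produce
# bit-identical state (a tested invariant).  Run it only on small instances:
# it is deliberately simple, not fast.

#' Initialise a simulation state
#'
#' Draws the initial patient population (opinions from the truncated normal,
#' ages staggered uniformly over the lifetime so that replacement is not
#' synchronised across the whole population) and an all-committed doctor
#' pool; the message pool starts empty.  Consumes the current R random
#' stream: call `set.seed()` first for reproducibility.
#'
#' @param params An [model_params()] record.
#' @return A state list with fields `tick`, `p_op`, `p_age`, `doctors`
#'   (list of `opinion`, `uncommitted`), `msg_op`, `msg_age`, `msg_init`,
#'   `ndu`.
#' @export
engine_init_state <- function(params) {
  np <- params$n_patients
  p_op <- draw_initial_opinion(np, params)
  p_age <- vapply(seq_len(np),
                  function(i) rint(as.integer(params$patient_lifetime)) - 1,
                  numeric(1))
  cr <- params$committed_doctor_opinion_range
  d_op <- vapply(seq_len(params$n_doctors),
                 function(i) stats::runif(1, cr[1], cr[2]), numeric(1))
  list(tick = 0L,
       p_op = p_op,
       p_age = p_age,
       doctors = list(opinion = d_op,
                      uncommitted = rep(FALSE, params$n_doctors)),
       msg_op = numeric(0),
       msg_age = integer(0),
       msg_init = logical(0),
       ndu = 0L)
}

# scalar opinion update for patient i against source opinion os;
# activist status for filtering is evaluated from the *current* opinion
ref_update_patient <- function(state, i, os, is_msg, params) {
  oi <- state$p_op[i]
  f <- filtering_factor(oi, os, oi < params$activism_threshold, is_msg,
                        params)
  state$p_op[i] <- update_opinion(oi, os, params$alpha, f)
  state
}

#' Age patients and messages, replacing expired patients
#'
#' Non-activist patients age by 1 tick, activists by
#' `activist_aging_factor` (status as of tick start).  A patient whose age
#' reaches `patient_lifetime` is replaced by a fresh agent (new truncated
#' normal opinion, age 0), keeping the patient count constant.  Messages
#' age by 1 and are removed (not replaced) at `message_lifetime`.
#'
#' @param state A state list (see [engine_init_state()]).
#' @param params An [model_params()] record.
#' @param activist Logical vector of tick-start activist flags; computed
#'   from current opinions when `NULL`.
#' @return The updated state.
#' @export
age_and_replace <- function(state, params, activist = NULL) {
  if (is.null(activist)) activist <- state$p_op < params$activism_threshold
  for (i in seq_len(params$n_patients)) {
    state$p_age[i] <- state$p_age[i] +
      if (activist[i]) params$activist_aging_factor else 1
    if (state$p_age[i] >= params$patient_lifetime) {
      state$p_op[i] <- draw_one_initial_opinion(params)
      state$p_age[i] <- 0
    }
  }
  if (length(state$msg_age)) {
    state$msg_age <- state$msg_age + 1L
    keep <- state$msg_age < params$message_lifetime
    state$msg_op <- state$msg_op[keep]
    state$msg_age <- state$msg_age[keep]
    state$msg_init <- state$msg_init[keep]
  }
  state
}

# append one message respecting the optional pool cap; returns list(state,
# added flag)
ref_append_message <- function(state, op, from_initiator, params) {
  if (!is.null(params$message_cap) &&
      length(state$msg_op) >= params$message_cap) {
    return(list(state = state, added = FALSE))
  }
  state$msg_op <- c(state$msg_op, op)
  state$msg_age <- c(state$msg_age, 0L)
  state$msg_init <- c(state$msg_init, from_initiator)
  list(state = state, added = TRUE)
}

#' Message-writing process
#'
#' Every initiator and every tick-start activist makes
#' `max_messages_per_author_per_tick` independent Bernoulli(PW) writing
#' attempts; each success appends a message cloning the author's current
#' opinion (age 0).  When a `message_cap` is set, writes beyond the cap are
#' discarded (newest rejected) and not counted.
#'
#' @inheritParams age_and_replace
#' @return `list(state, n_new, n_new_total)` where `n_new` excludes
#'   initiator-authored messages and `n_new_total` includes them.
#' @export
write_messages <- function(state, params, activist = NULL) {
  if (is.null(activist)) activist <- state$p_op < params$activism_threshold
  pw <- params$writing_probability
  mm <- params$max_messages_per_author_per_tick
  n_init <- 0L
  for (ii in seq_len(params$n_initiators)) {
    for (t in seq_len(mm)) {
      if (stats::runif(1) < pw) {
        res <- ref_append_message(state, params$initiator_opinion, TRUE,
                                  params)
        state <- res$state
        if (res$added) n_init <- n_init + 1L
      }
    }
  }
  n_act <- 0L
  for (i in seq_len(params$n_patients)) {
    if (activist[i]) {
      for (t in seq_len(mm)) {
        if (stats::runif(1) < pw) {
          res <- ref_append_message(state, state$p_op[i], FALSE, params)
          state <- res$state
          if (res$added) n_act <- n_act + 1L
        }
      }
    }
  }
  list(state = state, n_new = n_act, n_new_total = n_act + n_init)
}

#' Doctor-visit process
#'
#' Each patient independently visits a uniform random doctor with
#' probability PVD.  A committed doctor updates the patient directly (not
#' as a message source); an uncommitted doctor deflects the patient to a
#' uniform random message from the pool (message filtering semantics); an
#' empty pool leaves the patient unchanged.
#'
#' @inheritParams age_and_replace
#' @return The updated state.
#' @export
doctor_visit_process <- function(state, params) {
  pvd <- params$doctor_visit_ratio
  for (i in seq_len(params$n_patients)) {
    if (stats::runif(1) < pvd) {
      d <- rint(params$n_doctors)
      if (!state$doctors$uncommitted[d]) {
        state <- ref_update_patient(state, i, state$doctors$opinion[d],
                                    FALSE, params)
      } else if (length(state$msg_op) > 0) {
        m <- rint(length(state$msg_op))
        state <- ref_update_patient(state, i, state$msg_op[m], TRUE, params)
      }
    }
  }
  state
}

#' External-exposure process
#'
#' All patients, in a fresh uniform random permutation, each encounter one
#' source drawn uniformly among the pooled candidate entities: every
#' doctor, every other patient and every active message.  The chance of
#' meeting a message therefore grows with the size of the message pool,
#' which is the nonlinear feedback channel behind activity bursts.
#' Updates are sequential: a patient updated earlier in the permutation
#' exposes its new opinion to later patients.
#'
#' @inheritParams age_and_replace
#' @return The updated state.
#' @export
external_exposure_process <- function(state, params) {
  np <- params$n_patients
  perm <- seq_len(np)
  if (np >= 2) {
    for (i in np:2) {
      j <- rint(i)
      tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    }
  }
  nm <- length(state$msg_op)
  nd <- params$n_doctors
  # source drawn uniformly over the pooled entities (doctors, the other
  # patients, active messages): message influence scales with pool size
  total <- nd + (np - 1L) + nm
  for (k in seq_len(np)) {
    i <- perm[k]
    pick <- rint(total)
    if (pick <= nd) {
      state <- ref_update_patient(state, i, state$doctors$opinion[pick],
                                  FALSE, params)
    } else if (pick <= nd + np - 1L) {
      j <- pick - nd
      if (j >= i) j <- j + 1L
      state <- ref_update_patient(state, i, state$p_op[j], FALSE, params)
    } else {
      m <- pick - nd - (np - 1L)
      state <- ref_update_patient(state, i, state$msg_op[m], TRUE, params)
    }
  }
  state
}

#' One full simulation tick (reference semantics)
#'
#' Executes, in order: (0) doctor-commitment refresh against the previous
#' tick's antivaxxer count, (1) ageing and replacement, (2) message
#' writing, (3) doctor visits, (4) external exposure; then computes the
#' tick metrics from the post-update state.  Activist status used by
#' ageing and writing is fixed once at tick start (after the refresh).
#'
#' @inheritParams age_and_replace
#' @return `list(state, metrics)` where `metrics` is a one-row data frame
#'   with columns `tick`, `new_messages` (excluding initiator-authored),
#'   `new_messages_total`, `active_messages`, `n_antivax`, `n_activists`,
#'   `n_uncommitted_doctors`, `mean_opinion`.
#' @export
simulation_tick <- function(state, params) {
  state$tick <- state$tick + 1L
  nav_prev <- sum(state$p_op < params$vaccination_threshold)
  state$doctors <- refresh_doctor_commitment(state$doctors, nav_prev, params)
  state$ndu <- sum(state$doctors$uncommitted)
  activist <- state$p_op < params$activism_threshold
  state <- age_and_replace(state, params, activist)
  wr <- write_messages(state, params, activist)
  state <- wr$state
  state <- doctor_visit_process(state, params)
  state <- external_exposure_process(state, params)
  metrics <- data.frame(
    tick = state$tick,
    new_messages = wr$n_new,
    new_messages_total = wr$n_new_total,
    active_messages = length(state$msg_op),
    n_antivax = sum(state$p_op < params$vaccination_threshold),
    n_activists = sum(state$p_op < params$activism_threshold),
    n_uncommitted_doctors = state$ndu,
    mean_opinion = mean(state$p_op)
  )
  list(state = state, metrics = metrics)
}

# full reference run, used by run_simulation(engine = "reference")
run_engine_reference <- function(state, params, n_ticks, early_stop,
                                 success_threshold, confirm_ticks) {
  rows <- vector("list", n_ticks)
  runlen <- 0L
  t_used <- 0L
  for (t in seq_len(n_ticks)) {
    res <- simulation_tick(state, params)
    state <- res$state
    rows[[t]] <- res$metrics
    t_used <- t
    frac <- res$metrics$n_antivax / params$n_patients
    runlen <- if (frac >= success_threshold) runlen + 1L else 0L
    if (early_stop && runlen >= confirm_ticks) break
  }
  list(metrics = do.call(rbind, rows[seq_len(t_used)]), state = state)
}
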