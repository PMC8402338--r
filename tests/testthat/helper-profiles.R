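# Shared parameter profiles for tests.  `tiny_params()` is small enough for
# the pure-R reference engine; `small_params()` is for short compiled runs.

tiny_params <- function(...) {
  model_params(n_patients = 20L, n_doctors = 5L, n_initiators = 2L,
               max_ticks = 60L, ...)
}

small_params <- function(...) {
  model_params(n_patients = 200L, n_doctors = 20L, max_ticks = 500L, ...)
}

# build a bare engine state from explicit vectors (bypasses random init)
make_state <- function(p_op, p_age, d_op, d_unc,
                       msg_op = numeric(0), msg_age = integer(0),
                       msg_init = logical(0)) {
  list(tick = 0L, p_op = p_op, p_age = p_age,
       doctors = list(opinion = d_op, uncommitted = d_unc),
       msg_op = msg_op, msg_age = as.integer(msg_age),
       msg_init = msg_init, ndu = sum(d_unc))
}
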