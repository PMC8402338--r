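test_that("ageing replaces expired patients and expires messages", {
  p <- tiny_params(activism_threshold = -1.8)
  set.seed(1)
  st <- make_state(p_op = c(-1.9, rep(0, 19)),
                   p_age = c(89.5, rep(10, 19)),
                   d_op = rep(1.5, 5), d_unc = rep(FALSE, 5),
                   msg_op = rep(-1.9, 10), msg_age = rep(89L, 10))
  # activist ages by 0.5: 89.5 -> 90 >= lifetime -> replaced at age 0
  st1 <- age_and_replace(st, p)
  expect_equal(st1$p_age[1], 0)
  expect_true(st1$p_op[1] >= -2 && st1$p_op[1] <= 2)
  expect_equal(st1$p_age[2], 11)
  expect_length(st1$p_op, 20)              # NP conserved
  expect_length(st1$msg_op, 0)             # all messages aged out
  # non-activist at the same age survives one more tick
  st$p_op[1] <- 0
  st2 <- age_and_replace(st, p)
  expect_equal(st2$p_age[1], 0)  # 89.5 + 1 >= 90: replaced
})

test_that("message writing follows per-author Bernoulli trials", {
  # PW = 0: no messages ever
  p0 <- tiny_params(writing_probability = 0)
  st <- make_state(p_op = rep(0, 20), p_age = rep(0, 20),
                   d_op = rep(1.5, 5), d_unc = rep(FALSE, 5))
  set.seed(1)
  w <- write_messages(st, p0)
  expect_equal(w$n_new_total, 0)
  expect_length(w$state$msg_op, 0)
  # PW = 1, 5 initiators, no activists: exactly 25 messages per tick
  p1 <- model_params(n_patients = 20, n_doctors = 5, n_initiators = 5,
                     writing_probability = 1)
  set.seed(1)
  w1 <- write_messages(st, p1)
  expect_equal(w1$n_new_total, 25)
  expect_equal(w1$n_new, 0)
  expect_true(all(w1$state$msg_init))
  expect_true(all(w1$state$msg_op == p1$initiator_opinion))
  # mean output: (NI + NA) * 5 * PW per tick
  p2 <- model_params(n_patients = 30, n_doctors = 5, n_initiators = 5,
                     writing_probability = 0.45)
  st2 <- make_state(p_op = c(rep(-1.9, 20), rep(1, 10)), p_age = rep(0, 30),
                    d_op = rep(1.5, 5), d_unc = rep(FALSE, 5))
  set.seed(7)
  tot <- replicate(400, {
    w <- write_messages(st2, p2)
    w$n_new_total
  })
  expect_equal(mean(tot), (5 + 20) * 5 * 0.45, tolerance = 0.03)
})

test_that("message cap bounds the pool and discards newest writes", {
  p <- model_params(n_patients = 20, n_doctors = 5, n_initiators = 5,
                    writing_probability = 1, message_cap = 12)
  st <- make_state(p_op = rep(0, 20), p_age = rep(0, 20),
                   d_op = rep(1.5, 5), d_unc = rep(FALSE, 5))
  set.seed(1)
  w <- write_messages(st, p)
  expect_equal(length(w$state$msg_op), 12)
  expect_equal(w$n_new_total, 12)
})

test_that("doctor visits update toward committed doctors or deflect to messages", {
  # PVD = 0 is a no-op
  p0 <- tiny_params(doctor_visit_ratio = 0)
  st <- make_state(p_op = rep(0, 20), p_age = rep(0, 20),
                   d_op = rep(1.5, 5), d_unc = rep(FALSE, 5))
  set.seed(1)
  expect_equal(doctor_visit_process(st, p0)$p_op, st$p_op)
  # neutral patient, committed doctor at 1.5, guaranteed visit:
  # 0 * 0.34 + 1.5 * 0.66 = 0.99
  p1 <- model_params(n_patients = 1, n_doctors = 3, doctor_visit_ratio = 1)
  st1 <- make_state(p_op = 0, p_age = 0, d_op = rep(1.5, 3),
                    d_unc = rep(FALSE, 3))
  set.seed(1)
  expect_equal(doctor_visit_process(st1, p1)$p_op, 0.99)
  # uncommitted doctor with an empty pool leaves the patient unchanged
  st2 <- make_state(p_op = 0.4, p_age = 0, d_op = rep(-0.1, 3),
                    d_unc = rep(TRUE, 3))
  set.seed(1)
  expect_equal(doctor_visit_process(st2, p1)$p_op, 0.4)
  # uncommitted doctor deflects to the message pool (message semantics)
  st3 <- make_state(p_op = 0.4, p_age = 0, d_op = rep(-0.1, 3),
                    d_unc = rep(TRUE, 3), msg_op = -1.9, msg_age = 0L,
                    msg_init = TRUE)
  set.seed(1)
  expect_equal(doctor_visit_process(st3, p1)$p_op,
               0.4 * 0.34 + (-1.9) * 0.66)
})

test_that("with only pro sources opinions drift upward", {
  p <- model_params(n_patients = 50, n_doctors = 10, n_initiators = 0,
                    writing_probability = 0, doctor_hesitancy_factor = 0.001,
                    max_ticks = 300)
  r <- run_simulation(p, seed = 5)
  m <- r$metrics
  expect_gt(m$mean_opinion[300], 1)
  expect_gt(m$mean_opinion[300], m$mean_opinion[1])
  expect_true(all(m$n_uncommitted_doctors == 0))
  expect_false(r$av_success)
})

test_that("AV-success detection handles step, ramp and flat series", {
  flat <- rep(0, 300)
  d0 <- detect_av_success(flat, confirm_ticks = 90)
  expect_false(d0$av_success)
  expect_true(is.na(d0$transition_time))
  # step: both thresholds crossed at the same tick -> duration 0
  step <- c(rep(0, 99), rep(1, 150))
  d1 <- detect_av_success(step, confirm_ticks = 90)
  expect_true(d1$av_success)
  expect_equal(d1$transition_time, 100L)
  expect_equal(d1$transition_duration, 0L)
  # ramp: last at/below 0.5 at tick 9, first >= 0.95 at tick 90
  ramp <- c(rep(0.3, 9), seq(0.55, 0.95, length.out = 81), rep(0.96, 120))
  d2 <- detect_av_success(ramp, confirm_ticks = 90)
  expect_true(d2$av_success)
  expect_equal(d2$transition_time, 90L)
  expect_equal(d2$transition_duration, 80L)
  # a window shorter than confirm_ticks does not count
  blip <- c(rep(0, 50), rep(1, 60), rep(0, 100))
  expect_false(detect_av_success(blip, confirm_ticks = 90)$av_success)
})

test_that("runs are deterministic in (params, seed)", {
  p <- tiny_params()
  a <- run_simulation(p, seed = 11)
  b <- run_simulation(p, seed = 11)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$state$p_op, b$state$p_op)
  c <- run_simulation(p, seed = 12)
  expect_false(identical(a$metrics, c$metrics))
})

test_that("compiled engine and naive reference engine are bit-identical", {
  p <- model_params(n_patients = 20, n_doctors = 5, n_initiators = 2,
                    writing_probability = 0.45, activism_threshold = -1.8,
                    doctor_visit_ratio = 0.5, max_ticks = 50)
  a <- run_simulation(p, seed = 7, engine = "cpp", early_stop = FALSE)
  b <- run_simulation(p, seed = 7, engine = "reference", early_stop = FALSE)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$state$p_op, b$state$p_op)
  expect_identical(a$state$p_age, b$state$p_age)
  expect_identical(a$state$doctors$opinion, b$state$doctors$opinion)
  expect_identical(a$state$doctors$uncommitted, b$state$doctors$uncommitted)
  expect_identical(a$state$msg_op, b$state$msg_op)
  expect_identical(as.integer(a$state$msg_age), as.integer(b$state$msg_age))
  expect_identical(a$state$msg_init, b$state$msg_init)
  # and under an active message cap
  p2 <- update_params(p, message_cap = 15)
  a2 <- run_simulation(p2, seed = 9, engine = "cpp", early_stop = FALSE)
  b2 <- run_simulation(p2, seed = 9, engine = "reference", early_stop = FALSE)
  expect_identical(a2$metrics, b2$metrics)
  expect_identical(a2$state$p_op, b2$state$p_op)
  expect_true(all(a2$metrics$active_messages <= 15))
})

test_that("engine invariants hold along a stressed run", {
  p <- small_params(activism_threshold = -1.7, writing_probability = 0.6)
  r <- run_simulation(p, seed = 3, early_stop = FALSE)
  m <- r$metrics
  expect_true(all(m$n_activists <= m$n_antivax))
  expect_true(all(m$n_antivax <= p$n_patients))
  expect_true(all(m$n_uncommitted_doctors <= p$n_doctors))
  expect_true(all(m$mean_opinion >= -2 & m$mean_opinion <= 2))
  expect_length(r$state$p_op, p$n_patients)
  expect_true(all(abs(r$state$p_op) <= 2))
  expect_true(all(r$state$msg_age < p$message_lifetime))
})

test_that("no message stream means no AV success", {
  p <- model_params(n_patients = 100, n_doctors = 10, n_initiators = 0,
                    writing_probability = 0, max_ticks = 400)
  for (s in 1:2) expect_false(run_simulation(p, seed = s)$av_success)
})
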