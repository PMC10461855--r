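# Analysis operators: running averages, cycle detection, max frequency,
# response amplitude.

test_that("running_average is exact on constant and ramp signals", {
  sig <- make_signal(signal_spec("constant", offset = 3, horizon = 10))
  ra <- running_average(sig, "A")
  expect_true(all(abs(ra$average - 3) < 1e-12))

  ramp <- make_signal(signal_spec("ramp", offset = 0, slope = 1,
                                  horizon = 10))
  ra2 <- running_average(ramp, "A")
  expect_equal(ra2$average[nrow(ra2)], 5, tolerance = 1e-10)

  ## averages stay within the signal's range
  expect_true(all(ra2$average >= min(ramp$A) - 1e-12 &
                  ra2$average <= max(ramp$A) + 1e-12))
})

test_that("running_average of sin over a full period vanishes", {
  sig <- make_signal(signal_spec("sinusoid", amplitude = 1,
                                 period = 2 * pi, dt = 0.001,
                                 horizon = 2 * pi))
  ra <- running_average(sig, "A")
  expect_lt(abs(ra$average[nrow(ra)]), 1e-6)
})

test_that("running_average matches a high-resolution quadrature oracle", {
  f <- function(t) 2 + sin(2 * pi * t / 7) * exp(-0.03 * t)
  tt <- seq(0, 60, by = 0.01)
  tr <- tibble::tibble(time = tt, A = f(tt))
  ra <- running_average(tr, "A")
  want <- quad_mean_oracle(f, 0, 60)
  expect_lt(abs(ra$average[nrow(ra)] - want) / abs(want), 1e-4)
  ## nonzero origin
  ra2 <- running_average(tr, "A", t0 = 10)
  want2 <- quad_mean_oracle(f, 10, 60)
  expect_lt(abs(ra2$average[nrow(ra2)] - want2) / abs(want2), 1e-4)
  ## unknown species errors
  expect_error(running_average(tr, "B"), "not present")
  expect_error(running_average(tr, "A", t0 = -5), "span")
})

test_that("detect_cycles recovers programmed periods", {
  sig <- make_signal(signal_spec("sinusoid", amplitude = 2, period = 5,
                                 dt = 0.01, horizon = 60))
  cyc <- detect_cycles(sig, "A")
  expect_true(all(abs(cyc$period - 5) / 5 < 1e-3))
  expect_true(all(abs(cyc$frequency - 0.2) / 0.2 < 1e-3))
  expect_equal(cyc$frequency * cyc$period, rep(1, nrow(cyc)))

  damped <- make_signal(signal_spec("damped", amplitude = 2, period = 5,
                                    decay = 0.01, dt = 0.01,
                                    horizon = 100))
  cycd <- detect_cycles(damped, "A")
  expect_gt(nrow(cycd), 10)
  expect_true(all(abs(cycd$period - 5) / 5 < 0.005))
})

test_that("detect_cycles is invariant to time shifts and amplitude scaling", {
  base <- make_signal(signal_spec("sinusoid", amplitude = 1, period = 4,
                                  dt = 0.01, horizon = 40))
  shifted <- base
  shifted$time <- shifted$time + 123.4
  scaled <- base
  scaled$A <- base$A * 50
  c0 <- detect_cycles(base, "A")
  cs <- detect_cycles(shifted, "A")
  ck <- detect_cycles(scaled, "A")
  expect_equal(cs$period, c0$period, tolerance = 1e-10)
  expect_equal(cs$t_peak, c0$t_peak + 123.4, tolerance = 1e-8)
  expect_equal(ck$period, c0$period, tolerance = 1e-10)
})

test_that("non-oscillatory signals give an empty cycle table", {
  mono <- make_signal(signal_spec("step_relaxation", amplitude = -1,
                                  offset = 2, decay = 0.1, t_step = 0,
                                  horizon = 50))
  cyc <- detect_cycles(mono, "A")
  expect_s3_class(cyc, "hm_cycles")
  expect_equal(nrow(cyc), 0)
  expect_error(max_post_step_frequency(cyc, 10), "no complete cycles")
})

test_that("max_post_step_frequency picks the fastest post-step cycle", {
  cyc <- tibble::tibble(cycle = 1:4,
                        t_start = c(0, 10, 20, 30),
                        t_peak = c(10, 20, 30, 40),
                        period = c(5, 2, 3.3, 5),
                        frequency = c(0.2, 0.5, 0.3, 0.2),
                        peak = 1, trough = 0)
  expect_equal(max_post_step_frequency(cyc, 10), 0.5)
  ## cycles straddling the step are excluded
  expect_equal(max_post_step_frequency(cyc, 15), 0.3)
  ## constant series: the common inverse period
  cyc2 <- cyc
  cyc2$frequency <- 0.25
  expect_equal(max_post_step_frequency(cyc2, 0), 0.25)
})

test_that("delta_A returns the programmed excursion", {
  sig <- make_signal(signal_spec("step_relaxation", amplitude = -0.8,
                                 offset = 2, decay = 0.05, t_step = 50,
                                 horizon = 200))
  expect_equal(delta_A(sig, t_step = 50), 0.8, tolerance = 1e-9)
  ## flat trajectory: zero
  flat <- make_signal(signal_spec("constant", offset = 2, horizon = 50))
  expect_equal(delta_A(flat, t_step = 25), 0)
  ## invariant under time translation
  shifted <- sig
  shifted$time <- shifted$time + 1000
  expect_equal(delta_A(shifted, t_step = 1050), 0.8, tolerance = 1e-9)
  ## unsettled pre-step state warns but computes
  ramp <- make_signal(signal_spec("ramp", slope = 1, horizon = 10))
  expect_warning(delta_A(ramp, t_step = 5), "not settled")
})

test_that("oscillator averages converge to the analytic set-points", {
  fs <- figure_setup("fig5")
  tr <- simulate_model(fs$model, fs$state0,
                       schedules = step_schedule("k2", 100, 1, 10),
                       t_end = 1500)
  a_avg <- asymptotic_average(tr, "A", n_cycles = 100)
  e_avg <- asymptotic_average(tr, "E", n_cycles = 100)
  sp <- suppressWarnings(setpoints(fs$model))
  expect_equal(a_avg$value, sp$A_set, tolerance = 1e-3)
  ## <E> is held between the two outer set-points
  expect_gte(round(e_avg$value, 2), sp$E_set_I2)
  expect_lte(round(e_avg$value, 2), sp$E_set_I1)
})

test_that("harmonic_average_check validates the constant-A identity", {
  p <- default_params("m8_coherent_osc")
  tr <- tibble::tibble(time = seq(0, 100, 0.1), A = 7.5)
  out <- suppressWarnings(harmonic_average_check(tr, p))
  expect_equal(out$empirical, 1 / (p[["k10"]] + 7.5), tolerance = 1e-10)
  ## prediction is linear in k7
  p2 <- replace(p, "k7", p[["k7"]] * 2)
  out2 <- suppressWarnings(harmonic_average_check(tr, p2))
  expect_equal(out2$predicted, 2 * out$predicted)
})
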