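# Simulation engine: schedules, integration contract, pre-equilibration.

## A trivial linear system is obtained from the first-order motif-2
## scheme with everything but selected rates zeroed (Michaelis
## constants stay positive but multiply vanished fluxes).
.linear_fo <- function(k1 = 0, k2 = 0) {
  p <- default_params("m2_firstorder") * 0
  p[c("k5", "k7", "k13", "k16")] <- 1
  p["k1"] <- k1
  p["k2"] <- k2
  hm_model("m2_firstorder", params = p)
}
.zero_state <- c(A = 0, e = 0, E = 0, I1 = 0, I2 = 0)

test_that("constant-derivative and exponential-decay systems integrate exactly", {
  m <- .linear_fo(k1 = 1)
  tr <- simulate_model(m, .zero_state, t_end = 10, dt = 0.1)
  expect_equal(tr$A, tr$time, tolerance = 1e-8)

  m2 <- .linear_fo(k2 = 1)
  tr2 <- simulate_model(m2, replace(.zero_state, "A", 1), t_end = 1,
                        dt = 0.01)
  expect_equal(tr2$A[tr2$time == 1], exp(-1), tolerance = 1e-7)
})

test_that("schedules validate and segment the integration", {
  expect_error(schedule("k2", c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(schedule("k2", c(0, 1), c(1, -2)), "nonnegative")
  m <- .linear_fo(k1 = 1)
  expect_error(
    simulate_model(m, .zero_state, t_end = 1,
                   schedules = schedule("nope", 0, 1)),
    "unknown parameter")
  ## k1 stepping 1 -> 3 at t = 5: A(t) = t for t<=5, then 5 + 3(t-5)
  sch <- step_schedule("k1", 5, 1, 3)
  tr <- simulate_model(m, .zero_state, schedules = sch, t_end = 10,
                       dt = 0.1)
  expect_equal(tr$A[tr$time == 5], 5, tolerance = 1e-8)
  expect_equal(tr$A[tr$time == 10], 5 + 3 * 5, tolerance = 1e-7)
  expect_equal(attr(tr, "diagnostics")$n_segments, 2L)
})

test_that("segmented and straight-through integration agree", {
  fs <- figure_setup("fig11")
  m <- hm_model("m2_firstorder")
  sch <- step_schedule("k2", 50, 1, 10)
  tr_seg <- simulate_model(m, fs$states[["0"]], schedules = sch,
                           t_end = 100, dt = 0.1)
  tr_thr <- simulate_model(m, fs$states[["0"]], schedules = sch,
                           t_end = 100, dt = 0.1,
                           restart_at_breakpoints = FALSE)
  expect_equal(tr_seg$A, tr_thr$A, tolerance = 1e-5)
  expect_equal(tr_seg$E, tr_thr$E, tolerance = 1e-5)
})

test_that("tolerance refinement leaves the trajectory unchanged", {
  fs <- figure_setup("fig5")
  m <- fs$model
  sch <- step_schedule("k2", 20, 1, 10)
  tr1 <- simulate_model(m, fs$state0, schedules = sch, t_end = 40,
                        rtol = 1e-8, atol = 1e-10)
  tr2 <- simulate_model(m, fs$state0, schedules = sch, t_end = 40,
                        rtol = 5e-9, atol = 5e-11)
  ## halving the tolerances moves the state by far less than 10x the
  ## coarser tolerance relative to the signal scale
  expect_lt(max(abs(tr1$A - tr2$A)) / max(tr1$A), 1e-6)
})

test_that("the published first-order step run resettles at its set-points", {
  fs <- figure_setup("fig11")
  m <- hm_model("m2_firstorder")
  sch <- step_schedule("k2", 500, 1, 10)
  tr <- simulate_model(m, fs$states[["0"]], schedules = sch, t_end = 5000)
  expect_equal(tr$A[nrow(tr)], 2.0, tolerance = 1e-4)
  expect_equal(tr$E[nrow(tr)], 100, tolerance = 1e-4)
})

test_that("trajectory metadata records phases and clipping", {
  m <- .linear_fo(k1 = 1)
  sch <- step_schedule("k1", 5, 1, 3)
  tr <- simulate_model(m, .zero_state, schedules = sch, t_end = 10)
  snaps <- attr(tr, "params")
  expect_length(snaps, 2)
  expect_equal(snaps[[1]][["k1"]], 1)
  expect_equal(snaps[[2]][["k1"]], 3)
  expect_true(all(as.matrix(tr[, -1]) >= 0))
})

test_that("pre_equilibrate finds the non-oscillatory steady state", {
  m <- hm_model("m2_firstorder")
  st <- figure_setup("fig11")$states[["0"]]
  ## start displaced from the steady state
  st["A"] <- 1
  st["e"] <- 0.1
  eq <- pre_equilibrate(m, st, tol = 1e-6)
  expect_true(eq$converged)
  expect_equal(eq$state[["A"]], 2.0, tolerance = 1e-3)
  expect_equal(eq$state[["E"]], 100, tolerance = 1e-3)

  ## linear decay toward zero
  m0 <- .linear_fo(k2 = 1)
  eq0 <- pre_equilibrate(m0, replace(.zero_state, "A", 1))
  expect_true(eq0$converged)
  expect_lt(abs(eq0$state[["A"]]), 1e-6)
})

test_that("pre_equilibrate lands on the oscillator's limit cycle", {
  fs <- figure_setup("fig5")
  m <- fs$model
  eq <- pre_equilibrate(m, fs$state0, t_chunk = 100)
  expect_true(eq$converged)
  ## re-integrating from the returned state reproduces the period
  tr <- simulate_model(m, eq$state, t_end = 50)
  cyc <- detect_cycles(tr)
  expect_gt(nrow(cyc), 2)
  expect_lt(abs(mean(cyc$period) - eq$period) / eq$period, 1e-3)
})
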