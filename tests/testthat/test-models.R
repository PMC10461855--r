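# Model library: right-hand sides, set-points, validation.

test_that("m2 coherent RHS matches hand-substituted values", {
  m <- hm_model("m2_coherent_osc")
  ## reference state with everything but the derepression inflow and the
  ## k2 removal switched off
  d <- rhs_m2_coherent(c(A = 1, e = 0, E = 0, I1 = 0, I2 = 0), m$params)
  expect_equal(d[["A"]], 100 * 0.1 / 0.1 - 1 * 1 / (1e-6 + 1),
               tolerance = 1e-12)
  expect_equal(d[["A"]], 99.000, tolerance = 1e-4)
  ## production/removal balance of e
  d2 <- rhs_m2_coherent(c(A = 2, e = 0.1, E = 0, I1 = 0, I2 = 0),
                        replace(m$params, c("k4", "k9"), c(1, 20)))
  expect_equal(d2[["e"]], 0)
  ## zero state with zeroed sources -> all derivatives zero
  d3 <- rhs_m2_coherent(c(A = 0, e = 0, E = 0, I1 = 0, I2 = 0),
                        replace(m$params, c("k3", "k14"), c(0, 0)))
  expect_equal(unname(d3), rep(0, 5))
})

test_that("m8 coherent RHS matches hand substitution", {
  m <- hm_model("m8_coherent_osc")
  p <- m$params
  ## zero state: only the constant inflows survive
  d <- rhs_m8_coherent(c(A = 0, e = 0, E = 0, I1 = 0, I2 = 0),
                       replace(p, c("k1", "k3"), c(1, 0)))
  expect_equal(d[["A"]], 1)
  expect_equal(d[["e"]], p[["k6"]])        # k6*k10/(k10+0) = k6
  ## e production at the reference state, by direct substitution
  d2 <- rhs_m8_coherent(c(A = 1, e = 0, E = 0, I1 = 0, I2 = 0), p)
  expect_equal(d2[["e"]], p[["k6"]] * p[["k10"]] / (p[["k10"]] + 1))
  ## I2 zero-order balance: k15 = k16*E when I2 >> k17
  d3 <- rhs_m8_coherent(c(A = 0, e = 0, E = 1, I1 = 0, I2 = 1e3),
                        replace(p, c("k15", "k16"), c(50, 50)))
  expect_equal(d3[["I2"]], 50 - 50 * (1e3 / (1e-6 + 1e3)) * 1,
               tolerance = 1e-12)
})

test_that("first-order RHS vanishes at the published steady state", {
  m <- hm_model("m2_firstorder")
  st <- figure_setup("fig11")$states[["0"]]
  d <- rhs_m2_firstorder(st, m$params)
  biggest_flux <- 0.01 * st[["A"]] * st[["I1"]]   # kg*A*I1 term
  expect_lt(abs(d[["A"]]) / biggest_flux, 1e-3)
  expect_lt(max(abs(d[c("e", "E", "I1", "I2")])), 1e-3)
  ## doubling k2 from the steady state pulls A down
  d2 <- rhs_m2_firstorder(st, replace(m$params, "k2", 2))
  expect_lt(d2[["A"]], 0)
  ## only basal inflow
  p0 <- m$params * 0
  p0[c("k5", "k7", "k13", "k16")] <- 1   # keep Michaelis constants positive
  p0["k1"] <- 5
  d3 <- rhs_m2_firstorder(c(A = 0, e = 0, E = 0, I1 = 0, I2 = 0), p0)
  expect_equal(d3[["A"]], 5)
})

test_that("dual-E RHS balances where the set-points say it should", {
  m <- hm_model("dual_e")
  p <- m$params
  ## Ė2 balance at A = A_set_E2 = 2 with E2 >> k14
  d <- rhs_dual_e(c(A = 2, a = 0, E1 = 0, E2 = 100, I1 = 0, I2 = 0), p)
  expect_equal(d[["E2"]], 200 - 2 * 100 * (100 / (1e-5 + 100)),
               tolerance = 1e-10)
  ## full derepression of a's inflow at E1 = 0
  d2 <- rhs_dual_e(c(A = 0, a = 0, E1 = 0, E2 = 0, I1 = 0, I2 = 0), p)
  expect_equal(d2[["a"]], p[["k3"]])
  ## constructed steady state has a vanishing RHS (I2 drifts by design
  ## at +0.01, everything else balances)
  y <- steady_state(m)
  d3 <- rhs_dual_e(y, p)
  ## residuals at the Michaelis-correction scale (k14, k17, k20 ~ 1e-5)
  expect_lt(abs(d3[["A"]]), 1e-8)
  expect_lt(abs(d3[["a"]]), 1e-8)
  expect_lt(abs(d3[["E1"]]), 1e-3)
  expect_lt(abs(d3[["E2"]]), 1e-4)
  expect_lt(abs(d3[["I1"]]), 1e-3)
  expect_equal(d3[["I2"]], 0.01, tolerance = 1e-4)
})

test_that("incoherent RHS groups the precursor inflow as specified", {
  m <- hm_model("m2_incoherent_osc")
  p <- m$params
  ## A balance: k9*a = (k2+k10)*A
  d <- rhs_m2_incoherent(c(A = 2, a = 1, E = 0, I1 = 0, I2 = 0),
                         replace(p, c("k9", "k2", "k10"), c(2, 1, 0)))
  expect_equal(d[["A"]], 0)
  ## the a-inflow is (kg3*I2 + k3/(k5+E))*k5
  s <- c(A = 0, a = 0, E = 0, I1 = 0, I2 = 7)
  d2 <- rhs_m2_incoherent(s, p)
  expect_equal(d2[["a"]],
               (p[["kg3"]] * 7 + p[["k3"]] / (p[["k5"]] + 0)) * p[["k5"]],
               tolerance = 1e-12)
})

test_that("RHS equals the signed sum of individually evaluated fluxes", {
  for (name in model_names()) {
    m <- hm_model(name)
    for (seed in 1:20) {
      dr <- random_draw(m, seed + 1000 * match(name, model_names()))
      got <- m$rhs(dr$state, dr$params)
      want <- flux_oracle(name, dr$state, dr$params)
      expect_equal(unname(got), unname(want), tolerance = 1e-14)
    }
  }
})

test_that("compiled and R right-hand sides produce the same trajectories", {
  states <- list(
    m2_coherent_osc = figure_setup("fig5")$state0,
    m8_coherent_osc = figure_setup("fig9")$states[["0"]],
    m2_firstorder = figure_setup("fig11")$states[["0"]],
    dual_e = steady_state(hm_model("dual_e")),
    m2_incoherent_osc = figure_setup("fig16")$state0)
  for (name in model_names()) {
    m <- hm_model(name)
    trC <- simulate_model(m, states[[name]], t_end = 2, dt = 0.05,
                          compiled = TRUE)
    trR <- simulate_model(m, states[[name]], t_end = 2, dt = 0.05,
                          compiled = FALSE)
    for (sp in m$species) {
      expect_equal(trC[[sp]], trR[[sp]], tolerance = 1e-6)
    }
  }
})

test_that("nonnegativity is preserved at the RHS level", {
  ## with any one species at zero, its derivative is nonnegative once
  ## unconditional zero-order sources are accounted for: every removal
  ## term carries the species itself as a factor
  for (name in model_names()) {
    m <- hm_model(name)
    for (seed in 1:10) {
      dr <- random_draw(m, seed + 99)
      for (sp in m$species) {
        s0 <- dr$state
        s0[sp] <- 0
        d <- m$rhs(s0, dr$params)
        expect_gte(d[[sp]], 0)
      }
    }
  }
})

test_that("set-points reproduce the published values and close the loop", {
  sp2 <- setpoints(hm_model("m2_coherent_osc"))
  expect_equal(sp2$A_set, 2.0)
  expect_equal(sp2$E_set_I1, 5.0)
  expect_equal(sp2$E_set_I2, 4.99)
  ## plugging the set-point back into the zero-order balance: residual 0
  p <- hm_model("m2_coherent_osc")$params
  expect_identical(p[["k6"]] - p[["k4"]] * sp2$A_set, 0)
  expect_identical(p[["k12"]] - p[["k11"]] * sp2$E_set_I1, 0)
  expect_identical(p[["k14"]] - p[["k15"]] * sp2$E_set_I2, 0)

  sp8 <- setpoints(hm_model("m8_coherent_osc"))
  expect_equal(sp8$E_set_I1, 10)
  expect_equal(sp8$E_set_I2, 50)
  expect_true(is.na(sp8$A_set))
  expect_equal(sp8$inv_shifted_A_average, 50 / (1e3 * 2.5))

  spd <- setpoints(hm_model("dual_e"))
  expect_equal(spd$A_set_E1, 2.1)
  expect_equal(spd$A_set_E2, 2.0)
  expect_equal(spd$E2_set_I1, 100)
  expect_equal(spd$E2_set_I2, 99.99)

  ## trivial ratios
  m <- hm_model("m2_coherent_osc",
                params = c(k6 = 1, k4 = 1, k12 = 1, k11 = 1,
                           k14 = 0.5, k15 = 1))
  sp <- setpoints(m)
  expect_equal(unlist(sp), c(A_set = 1, E_set_I1 = 1, E_set_I2 = 0.5))
})

test_that("windup mis-ordering warns but does not error", {
  expect_warning(
    setpoints(hm_model("m2_coherent_osc", params = c(k14 = 6))),
    "windup")
  ## the first-order reference set has exactly equal E set-points
  expect_warning(setpoints(hm_model("m2_firstorder")), "windup")
  ## m8 ordering deliberately unchecked
  expect_no_warning(setpoints(hm_model("m8_coherent_osc")))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(hm_model("m2_coherent_osc", params = c(k99 = 1)), "unknown")
  expect_error(hm_model("m2_coherent_osc", params = c(k2 = -1)), "negative")
  expect_error(hm_model("m2_coherent_osc", params = c(k7 = 0)), "Michaelis")
  expect_error(hm_model("m2_coherent_osc", params = c(k2 = NaN)),
               "non-finite")
  m <- hm_model("m2_coherent_osc")
  expect_error(rhs_m2_coherent(c(A = 1, e = 1, E = Inf, I1 = 0, I2 = 0),
                               m$params), "non-finite")
  expect_error(rhs_m2_coherent(c(A = 1), m$params), "state")
  ## zero set-point denominator
  expect_error(setpoints(hm_model("m2_coherent_osc", params = c(k4 = 0))),
               "denominator")
})
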