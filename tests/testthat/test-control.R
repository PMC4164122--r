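test_that("ventilatory drive is additive in its saturating terms", {
  cp <- control_params(S_ref = 0.97, G_hyp = 100)
  # at the setpoints every drive term is zero
  expect_equal(ventilatory_drive(0.97, cp$B_CO2, 0, cp), cp$VE_rest)
  # saturation step 0.97 -> 0.80 adds G_hyp * 0.17 = 17 L/min
  expect_equal(ventilatory_drive(0.80, cp$B_CO2, 0, cp) -
                 ventilatory_drive(0.97, cp$B_CO2, 0, cp), 17)
  # exercise term k_ex * work
  expect_equal(ventilatory_drive(0.97, cp$B_CO2, 150, cp) - cp$VE_rest,
               0.25 * 150)
  # phasic component adds G_phasic * phasic and vanishes at steady state
  expect_equal(ventilatory_drive(0.80, cp$B_CO2, 0, cp, phasic = 0.1) -
                 ventilatory_drive(0.80, cp$B_CO2, 0, cp), cp$G_phasic * 0.1)
})

test_that("breathing pattern splits VE monotonically at fixed 35% inspiration", {
  p <- breathing_pattern(6)
  expect_equal(p$V_T, 500)
  expect_equal(p$Freq, 12)
  expect_equal(p$insp_fraction, 0.35)
  ve <- seq(4, 120, by = 2)
  pats <- lapply(ve, breathing_pattern)
  vt <- vapply(pats, `[[`, numeric(1), "V_T")
  fr <- vapply(pats, `[[`, numeric(1), "Freq")
  expect_true(all(diff(vt) >= 0))
  expect_true(all(diff(fr) >= -1e-12))
  expect_equal(vt * fr / 1000, ve, tolerance = 1e-12)  # V_T * Freq = VE
  expect_true(all(vt <= control_params()$VT_cap))
  expect_error(breathing_pattern(0), "positive")
})

test_that("metabolic demand and cardiac output are linear with saturation at Q_max", {
  d0 <- metabolic_demand(0)
  expect_equal(d0$VO2, 0.3)
  expect_equal(metabolic_demand(240)$VO2, 3.084)
  w <- c(0, 50, 120, 240)
  dem <- lapply(w, metabolic_demand)
  expect_equal(vapply(dem, `[[`, numeric(1), "VCO2") /
                 vapply(dem, `[[`, numeric(1), "VO2"),
               rep(0.85, 4))
  expect_equal(cardiac_output(1), 10)
  expect_equal(cardiac_output(10), 25)  # capped at Q_max
  # mass scaling of the resting terms
  expect_equal(metabolic_demand(0, body_mass = 35)$VO2, 0.15)
})

test_that("oxygen-deficit fatigue accumulates shortfall and crosses at D_max/r", {
  fp <- fatigue_params(D_max = 600)
  # delivery covers demand: deficit stays zero
  s <- fatigue_update(0, VO2_demand = 300, Q_Tot = 6000, C_a_O2 = 0.2,
                      dt = 10, params = fp)
  expect_equal(s$deficit, 0)
  expect_false(s$fatigued)
  # constant shortfall r: first crossing at D_max / r
  # demand 1000 ml/min, supply 6000 * (0.12 - 0.02) = 600 -> r = 400 ml/min
  dt <- 1; deficit <- 0; t <- 0
  repeat {
    s <- fatigue_update(deficit, 1000, 6000, 0.12, dt, fp)
    deficit <- s$deficit; t <- t + dt
    if (s$fatigued) break
  }
  expect_equal(t, 600 / 400 * 60, tolerance = dt / 60)
  expect_error(fatigue_update(0, 300, 6000, 0.2, 0), "positive")
})

test_that("treadmill protocol ramps speed and converts to workload", {
  expect_equal(sheep_ramp_speed(0), 0.67)
  expect_equal(sheep_ramp_speed(89.9), 0.67)
  expect_equal(sheep_ramp_speed(90), 0.89)
  expect_equal(sheep_ramp_speed(630), 0.67 + 7 * 0.22)
  expect_equal(sheep_ramp_speed(720), 2.22)
  expect_equal(sheep_ramp_speed(10000), 2.22)  # capped
  expect_equal(treadmill_work(2, 0, 40, c_level = 1.5), 120)
  expect_equal(treadmill_work(1, 9, 40, c_level = 1.5),
               40 * (1.5 + 9.81 * 0.09))
})

test_that("control parameters scale with body mass where volume-like", {
  cp <- control_params()
  sc <- scale_control_params(cp, 35)
  expect_equal(sc$VE_rest, cp$VE_rest / 2)
  expect_equal(sc$VT_rest, cp$VT_rest / 2)
  expect_equal(sc$k_ex, cp$k_ex)        # per-watt drive is mass-free
  expect_equal(sc$tau_up, cp$tau_up)    # dynamics unchanged
})
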