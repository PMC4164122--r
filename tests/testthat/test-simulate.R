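test_that("equilibrium state is a fixed point of the breath engine", {
  # inspired gas, alveoli, dead space, capillaries and venous blood all at the
  # same partial pressures, zero metabolism: one breath must change nothing
  lung <- make_fixture_lung(2, heights = c(30, 70))
  chem <- blood_chemistry(linear = TRUE, beta_linear = 0.003)
  st <- solver_settings(n_div = 6)
  P0_O2 <- 100; P0_CO2 <- 30
  env <- environment_air(FiO2 = P0_O2 / (760 - 47), FiCO2 = P0_CO2 / (760 - 47))
  ph <- init_physio(lung, env, chem, st)
  ph$engine$aw_C[] <- rep(c(P0_O2, P0_CO2) / PDM_RT, each = nrow(ph$engine$aw_C))
  ph$engine$ds_C[] <- rep(c(P0_O2, P0_CO2) / PDM_RT, each = 2)
  ph$engine$alv_C[] <- rep(c(P0_O2, P0_CO2) / PDM_RT, each = 2)
  cap <- array(ph$engine$cap_P, c(2, st$n_div, 2))
  cap[, , 1] <- P0_O2; cap[, , 2] <- P0_CO2
  ph$engine$cap_P <- as.numeric(cap)
  ph$engine$C_ven <- 0.003 * c(P0_O2, P0_CO2)
  out <- run_breath(lung, ph, settings = st, env = env, chem = chem,
                    V_T = 400, Freq = 15, Q_Tot = 5000, VO2 = 0, VCO2 = 0,
                    dl_fixed_o2 = 40, clamp_venous = TRUE)
  expect_equal(out$engine$alv_C, ph$engine$alv_C, tolerance = 1e-10)
  expect_equal(out$engine$aw_C, ph$engine$aw_C, tolerance = 1e-10)
  expect_equal(out$engine$cap_P, ph$engine$cap_P, tolerance = 1e-7)
  expect_equal(attr(out, "diag")$uptake, c(0, 0), tolerance = 1e-8)
})

test_that("resting oxygen uptake over a breath matches metabolic demand", {
  ss <- resting_ss()
  dg <- attr(ss$state, "diag")
  expected <- ss$VO2 * 1000 * dg$T_breath / 60
  expect_equal(dg$uptake[1], expected, tolerance = 0.02)
  # CO2 output likewise (sign: blood to alveoli)
  expect_equal(-dg$uptake[2], ss$VCO2 * 1000 * dg$T_breath / 60,
               tolerance = 0.02)
})

test_that("per-breath gas mass balance closes to solver precision", {
  ss <- resting_ss()
  dg <- attr(ss$state, "diag")
  expect_lt(abs(dg$residual[1]), 0.005 * abs(dg$uptake[1]))
  expect_lt(abs(dg$residual[2]), 0.005 * abs(dg$uptake[2]))
})

test_that("closed-loop rest sits in the physiologic envelope", {
  ss <- resting_ss()
  expect_gt(ss$P_a_O2, 85); expect_lt(ss$P_a_O2, 105)
  expect_gt(ss$P_a_CO2, 35); expect_lt(ss$P_a_CO2, 45)
  expect_gt(ss$VE, 5); expect_lt(ss$VE, 8)
  expect_equal(ss$VE, ss$V_T * ss$Freq / 1000, tolerance = 1e-12)
})

test_that("halving the time step barely moves the converged arterial oxygen", {
  lung <- human_lung()
  s1 <- steady_state(lung, solver = list(dt = 0.01))
  s2 <- steady_state(lung, solver = list(dt = 0.005))
  expect_lt(abs(s1$P_a_O2 - s2$P_a_O2), 0.2)
})

test_that("arterial oxygen falls strictly with shunt at steady state", {
  lung <- human_lung()
  s0 <- steady_state(lung, damage = uniform_damage(lung, 0, 0))
  s5 <- steady_state(lung, damage = uniform_damage(lung, 0.05, 0))
  expect_gt(s0$P_a_O2, s5$P_a_O2)
})

test_that("homogeneous lung reproduces the two-compartment analytic steady state", {
  # single-segment fixture, fixed ventilation/perfusion, venous content
  # clamped, large constant D_L so end-capillary blood equilibrates with the
  # alveolus; oracle: classic alveolar mass balance
  #   VA/RT (P_I - P_A) = Q (content(P_A) - C_v), solved by uniroot
  lung <- make_fixture_lung(1, airway_ml = 2)
  chem <- blood_chemistry()
  st <- solver_settings(n_div = 10)
  env <- environment_air()
  V_T <- 300; Freq <- 20; Q <- 5000; C_v <- o2_content(40, chem)
  ph <- init_physio(lung, env, chem, st)
  ph$engine$C_ven <- c(C_v, co2_content(46, chem))
  for (b in 1:50)
    ph <- run_breath(lung, ph, settings = st, env = env, chem = chem,
                     V_T = V_T, Freq = Freq, Q_Tot = Q, VO2 = 0, VCO2 = 0,
                     dl_fixed_o2 = 400, clamp_venous = TRUE)
  P_a_model <- content_to_pressure(attr(ph, "diag")$C_art_mean[1], "O2", chem)
  V_DS <- sum(lung$airways$volume_ml) + sum(pmax(lung$segments$deadspace_ml, 0.5))
  VA <- (V_T - V_DS) * Freq                    # ml/min BTPS
  P_I <- env$FiO2 * (env$P_B - 47)
  balance <- function(P_A)
    VA / PDM_RT * (P_I - P_A) - Q * (o2_content(P_A, chem) - C_v)
  P_analytic <- stats::uniroot(balance, c(5, P_I - 0.01), tol = 1e-10)$root
  expect_lt(abs(P_a_model - P_analytic), 1)
})

test_that("engine is deterministic and stable at coarse time steps", {
  cfg <- scenario_config(name = "det", duration_s = 45)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # backward-Euler sweeps survive dt up to a full inspiration time
  lung <- human_lung()
  ph <- init_physio(lung)
  coarse <- solver_settings(dt = 1.75)
  out <- run_breath(lung, ph, settings = coarse, V_T = 500, Freq = 12,
                    Q_Tot = 6000, VO2 = 300, VCO2 = 255)
  expect_true(all(is.finite(out$engine$alv_C)))
  expect_true(all(out$engine$alv_C >= 0))
  expect_true(all(is.finite(out$engine$cap_P)))
})

test_that("whole-body oxygen balance closes at steady state", {
  ss <- resting_ss()
  dg <- attr(ss$state, "diag")
  uptake_rate <- dg$uptake[1] / dg$T_breath * 60   # ml/min from the lung
  expect_equal(uptake_rate, ss$VO2 * 1000, tolerance = 0.01)
})

test_that("scenario output carries ordered time and consistent channels", {
  ts <- run_scenario(scenario_config(duration_s = 30))
  expect_true(all(diff(ts$time_s) > 0))
  expect_equal(ts$VE, ts$V_T * ts$Freq / 1000, tolerance = 1e-9)
  expect_true(all(ts$SaO2 >= 0 & ts$SaO2 <= 1))
  path <- tempfile(fileext = ".csv")
  write_timeseries_csv(ts, path)
  hdr <- readLines(path, n = 5)
  expect_true(all(startsWith(hdr, "#")))
  body <- utils::read.csv(path, comment.char = "#")
  expect_equal(nrow(body), nrow(ts))
})
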