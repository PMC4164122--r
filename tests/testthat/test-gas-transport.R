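test_that("implicit airway step is bounded, stable and first-order accurate", {
  expect_equal(airway_step(0.1, 0.5, flow = 0, V = 50, dt = 0.01), 0.1)
  expect_equal(airway_step(0.3, 0.3, flow = 80, V = 50, dt = 0.01), 0.3)
  expect_equal(airway_step(0, 1, flow = 100, V = 100, dt = 0.01), 0.01 / 1.01)
  # bounded between old and inlet even for huge steps
  expect_lt(airway_step(0, 1, flow = 1e5, V = 10, dt = 1), 1)
  expect_error(airway_step(-0.1, 0.2, 1, 1, 0.01), "non-negative")
  # washout against the closed form C(t) = 1 - exp(-t flow/V):
  washout <- function(dt) {
    C <- 0
    for (i in seq_len(round(1 / dt))) C <- airway_step(C, 1, 100, 100, dt)
    C
  }
  exact <- 1 - exp(-1)
  e1 <- abs(washout(0.02) - exact)
  e2 <- abs(washout(0.01) - exact)
  expect_gt(e1 / e2, 1.8)  # error halves with dt: observed order >= 1
})

test_that("workload-dependent O2 diffusing capacity evaluates as specified", {
  expect_equal(dl_oxygen(0, 0), 76)
  expect_equal(dl_oxygen(100, 0), 28)
  expect_equal(dl_oxygen(100, 150), -78 + (0.3 + 150 / 833) * 100 + 76 + 25)
  # pressure argument clamps at the validity boundary; floor guards below
  expect_equal(dl_oxygen(150, 0), dl_oxygen(110, 0))
  expect_gte(dl_oxygen(110, 0), 1)
  expect_error(dl_oxygen(-1, 0), "non-negative")
  expect_error(dl_oxygen(50, -10), "non-negative")
})

test_that("Hill saturation and content inversion behave like a dissociation curve", {
  chem <- blood_chemistry()
  expect_equal(o2_saturation(chem$P50, chem), 0.5)
  expect_equal(o2_saturation(0, chem), 0)
  expect_equal(o2_saturation(100, chem), 0.972, tolerance = 5e-4)
  # monotone and invertible across the physiologic range
  P <- seq(0.5, 600, length.out = 60)
  cont <- o2_content(P, chem)
  expect_true(all(diff(cont) > 0))
  expect_equal(content_to_pressure(cont, "O2", chem), P, tolerance = 1e-6)
  Pc <- seq(10, 120, length.out = 20)
  expect_equal(content_to_pressure(co2_content(Pc, chem), "CO2", chem), Pc,
               tolerance = 1e-10)
  expect_error(content_to_pressure(10, "O2", chem), "maximum")
})

test_that("alveolar step reduces to its degenerate forms", {
  alv <- list(C = 0.12, V = 150)
  # no diffusion during exhale: concentration frozen, volume falls
  out <- alveolar_step(alv, "exhale", flow = 50, P_c = 40, D_L = 0, dt = 0.01)
  expect_equal(out$C, alv$C)
  expect_equal(out$V, alv$V - 0.5)
  # diffusion equilibrium: P_c = C*RT gives zero flux, dilution only
  out2 <- alveolar_step(alv, "inhale", C_aw = alv$C, flow = 50,
                        P_c = alv$C * PDM_RT, D_L = 20, dt = 0.01)
  expect_equal(out2$C, alv$C, tolerance = 1e-12)
  expect_equal(out2$transfer, 0, tolerance = 1e-12)
  expect_error(alveolar_step(list(C = 0.1, V = 2), "exhale", flow = 200,
                             dt = 0.01), "underflow")
})

test_that("alveolar step matches an independent stiff integration", {
  skip_if_not_installed("deSolve")
  # inhale at constant feeding concentration, fixed capillary pressure,
  # integrated over 0.5 s; oracle is lsoda on the same ODE
  C_aw <- 0.16; P_c <- 50; D_L <- 30; flow <- 400; V0 <- 150; C0 <- 0.11
  rhs <- function(t, y, p) {
    V <- V0 + flow * t
    dC <- (flow * (C_aw - y[1]) - (D_L / 60) * (y[1] * PDM_RT - P_c)) / V
    list(dC)
  }
  oracle <- deSolve::lsoda(c(C = C0), seq(0, 0.5, by = 0.05), rhs, NULL,
                           rtol = 1e-10, atol = 1e-12)
  alv <- list(C = C0, V = V0)
  for (i in seq_len(500))
    alv <- alveolar_step(alv, "inhale", C_aw = C_aw, flow = flow, P_c = P_c,
                         D_L = D_L, dt = 0.001)
  expect_equal(alv$C, unname(oracle[nrow(oracle), "C"]), tolerance = 1e-3)
  expect_equal(alv$V, V0 + flow * 0.5)
})

test_that("capillary train reproduces the linear-chemistry closed form", {
  chem <- blood_chemistry(linear = TRUE, beta_linear = 0.003)
  tr <- capillary_train(n = 10, V_capillary = 75, f_k = 0.05, Q_c = 250,
                        P_init = 40, gas = "O2", chem = chem)
  P_Alv <- 100; D_L_eff <- 0.05 * 40; inlet <- 0.003 * 40
  # drive the implicit sweep to steady state
  for (i in seq_len(400)) tr <- capillary_step(tr, inlet, P_Alv, D_L_eff, dt = 0.5)
  closed <- capillary_steady_linear(tr, inlet, P_Alv, D_L_eff)
  expect_equal(tr$C, closed, tolerance = 1e-10)
  # geometric approach of division pressures toward the alveolar value
  gaps <- P_Alv - tr$P
  ratio <- gaps[-1] / gaps[-length(gaps)]
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-8)
})

test_that("capillary limits: no exchange and diffusion equilibrium", {
  chem <- blood_chemistry()
  tr <- capillary_train(n = 8, V_capillary = 75, f_k = 0.05, Q_c = 250,
                        P_init = 40, chem = chem)
  inlet <- o2_content(40, chem)
  for (i in seq_len(300)) tr <- capillary_step(tr, inlet, 100, 0, dt = 0.5)
  expect_equal(tr$C[tr$n], inlet, tolerance = 1e-9)   # D_L = 0: no exchange
  tr2 <- capillary_train(n = 8, V_capillary = 75, f_k = 0.05, Q_c = 250,
                         P_init = 40, chem = chem)
  for (i in seq_len(300)) tr2 <- capillary_step(tr2, inlet, 100, 5000, dt = 0.5)
  expect_lt(abs(tr2$P[tr2$n] - 100), 0.1)             # huge D_L: equilibration
})

test_that("combined-coefficient capillary update equals its factored form", {
  # the per-division coefficients n*Q/(V_cap*f) and D_L/V_cap must equal the
  # update built from division volume V_c = V_cap*f/n and flow Q_c directly
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    V_cap <- runif(1, 40, 120); f_k <- runif(1, 0.02, 0.3)
    Q_c <- runif(1, 100, 600); beta <- runif(1, 0.001, 0.01)
    dt <- runif(1, 0.005, 0.05); P_Alv <- runif(1, 40, 110)
    D_L <- runif(1, 1, 50) * f_k
    chem <- blood_chemistry(linear = TRUE, beta_linear = beta)
    tr <- capillary_train(n, V_cap, f_k, Q_c, P_init = runif(1, 20, 60),
                          chem = chem)
    C_in <- beta * runif(1, 20, 60)
    stepped <- capillary_step(tr, C_in, P_Alv, D_L, dt)
    # direct backward-Euler on the factored equation, division by division
    V_c <- V_cap * f_k / n; q <- Q_c / 60; g <- (D_L / n) / 60
    C_prev <- C_in; C_ref <- numeric(n)
    for (i in seq_len(n)) {
      a <- q * dt / V_c; b <- g * dt / V_c
      C_ref[i] <- (tr$C[i] + a * C_prev + b * P_Alv) / (1 + a + b / beta)
      C_prev <- C_ref[i]
    }
    expect_equal(stepped$C, C_ref, tolerance = 1e-12)
  }
})

test_that("arterial mixing is the shunt-weighted average", {
  expect_equal(mix_arterial(c(0.2, 0.2), c(0.5, 0.5), 0.15, shunt = 0), 0.2)
  expect_equal(mix_arterial(c(0.2, 0.2), c(0.5, 0.5), 0.15, shunt = 1), 0.15)
  expect_equal(mix_arterial(rep(0.20, 4), rep(0.25, 4), 0.15, shunt = 0.15),
               0.1925)
  expect_error(mix_arterial(c(0.2, 0.2), c(0.5), 0.15, 0), "equal length")
  expect_error(mix_arterial(0.2, 1, 0.15, 1.5), "0, 1")
})
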