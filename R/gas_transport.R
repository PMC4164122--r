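# Airway / alveolar / capillary gas exchange primitives.
#
# Unit conventions: pressures mmHg; volumes ml; gas amounts ml STPD; airway
# and alveolar flows ml/s; diffusing capacities and blood flows cross the API
# in ml/(mmHg*min) and ml/min respectively and are converted to per-second
# internally. Gas-phase concentration C (ml STPD per ml of compartment volume
# at body conditions) converts to partial pressure by P = C * RT with
# RT = 760 * 310/273 = 863 mmHg (dry-gas, body-temperature conversion).

#' @export
PDM_RT <- 760 * 310 / 273  # mmHg per (ml STPD / ml), body temperature

#' Blood chemistry parameter set
#'
#' Oxygen is carried by hemoglobin with a Hill saturation curve plus a small
#' dissolved fraction; carbon dioxide content is linearized over the
#' physiologic range (Douglas-type line). A fully linear option
#' (`content = beta * P` for both gases) is provided for analytic test
#' fixtures.
#'
#' @param Hb Hemoglobin, g/dl.
#' @param P50 O2 pressure at half saturation, mmHg.
#' @param hill_n Hill exponent.
#' @param o2_capacity ml O2 per g hemoglobin at full saturation.
#' @param beta_O2 Dissolved O2 solubility, ml/(ml*mmHg).
#' @param co2_intercept,co2_slope Linear CO2 content curve
#'   `C = intercept + slope * P` (ml/ml, ml/(ml*mmHg)).
#' @param linear If `TRUE`, both gases use `content = beta * P`.
#' @param beta_linear Solubility used when `linear = TRUE`.
#' @return An object of class `blood_chemistry`.
#' @export
blood_chemistry <- function(Hb = 15, P50 = 26.8, hill_n = 2.7,
                            o2_capacity = 1.34, beta_O2 = 0.00003,
                            co2_intercept = 0.2, co2_slope = 0.007,
                            linear = FALSE, beta_linear = 0.003) {
  structure(list(Hb = Hb, P50 = P50, hill_n = hill_n,
                 o2_capacity = o2_capacity, beta_O2 = beta_O2,
                 co2_intercept = co2_intercept, co2_slope = co2_slope,
                 linear = linear, beta_linear = beta_linear),
            class = "blood_chemistry")
}

#' Oxygen-hemoglobin saturation (Hill form)
#'
#' `S = P^n / (P^n + P50^n)`; `S(P50) = 0.5` by construction.
#'
#' @param P_O2 Oxygen partial pressure, mmHg (>= 0). Vectorized.
#' @param chem A [blood_chemistry()] object.
#' @return Saturation fraction in \[0, 1).
#' @export
o2_saturation <- function(P_O2, chem = blood_chemistry()) {
  if (any(!is.finite(P_O2)) || any(P_O2 < 0))
    stop_invalid("P_O2 must be non-negative")
  P_O2^chem$hill_n / (P_O2^chem$hill_n + chem$P50^chem$hill_n)
}

#' Blood oxygen content
#'
#' Hemoglobin-bound plus dissolved oxygen:
#' `content = capacity * Hb/100 * S(P) + beta_O2 * P` (ml STPD per ml blood).
#'
#' @inheritParams o2_saturation
#' @return Content, ml O2 / ml blood.
#' @export
o2_content <- function(P_O2, chem = blood_chemistry()) {
  if (chem$linear) return(chem$beta_linear * P_O2)
  chem$o2_capacity * chem$Hb / 100 * o2_saturation(P_O2, chem) +
    chem$beta_O2 * P_O2
}

#' Blood carbon dioxide content (linearized curve)
#'
#' @param P_CO2 CO2 partial pressure, mmHg (>= 0). Vectorized.
#' @inheritParams o2_saturation
#' @return Content, ml CO2 / ml blood.
#' @export
co2_content <- function(P_CO2, chem = blood_chemistry()) {
  if (any(!is.finite(P_CO2)) || any(P_CO2 < 0))
    stop_invalid("P_CO2 must be non-negative")
  if (chem$linear) return(chem$beta_linear * P_CO2)
  chem$co2_intercept + chem$co2_slope * P_CO2
}

#' Invert a blood content curve to partial pressure
#'
#' The content curves are continuous and strictly increasing, so the inverse
#' is well defined; the O2 inverse is found by bracketed root finding.
#'
#' @param content Gas content, ml/ml (scalar or vector).
#' @param gas `"O2"` or `"CO2"`.
#' @inheritParams o2_saturation
#' @return Partial pressure, mmHg.
#' @export
content_to_pressure <- function(content, gas = c("O2", "CO2"),
                                chem = blood_chemistry()) {
  gas <- match.arg(gas)
  if (any(!is.finite(content)) || any(content < 0))
    stop_invalid("content must be non-negative and finite")
  if (chem$linear) return(content / chem$beta_linear)
  if (gas == "CO2") {
    p <- (content - chem$co2_intercept) / chem$co2_slope
    return(pmax(p, 0))
  }
  p_max <- 1500
  c_max <- o2_content(p_max, chem)
  vapply(content, function(ci) {
    if (ci > c_max)
      stop_invalid("O2 content ", signif(ci, 4), " exceeds physical maximum")
    if (ci == 0) return(0)
    stats::uniroot(function(p) o2_content(p, chem) - ci,
                   lower = 0, upper = p_max, tol = 1e-12)$root
  }, numeric(1))
}

#' Workload-dependent oxygen diffusing capacity
#'
#' Quadratic dependence of whole-lung membrane D_L for oxygen on alveolar O2
#' pressure and exercise load:
#' `D_L = -0.0078 P^2 + (0.3 + Work/833) P + 76 + Work/6`
#' (ml/(mmHg*min)). The quadratic is a regression over the physiologic
#' alveolar-oxygen range and turns negative when extrapolated to high
#' pressures; the pressure argument is therefore clamped at `p_valid`
#' (beyond which the boundary value is held — non-negative for all
#' workloads), and the result is additionally floored at `floor_value`.
#'
#' @param P_Alv_O2 Alveolar O2 partial pressure, mmHg (>= 0). Vectorized.
#' @param work Exercise load, W (>= 0).
#' @param floor_value Minimum returned D_L, ml/(mmHg*min).
#' @param p_valid Upper bound of the relation's pressure range, mmHg.
#' @return D_L for O2, ml/(mmHg*min).
#' @export
dl_oxygen <- function(P_Alv_O2, work = 0, floor_value = 1, p_valid = 110) {
  if (any(!is.finite(P_Alv_O2)) || any(P_Alv_O2 < 0))
    stop_invalid("P_Alv_O2 must be non-negative")
  if (any(!is.finite(work)) || any(work < 0))
    stop_invalid("work must be non-negative")
  P <- pmin(P_Alv_O2, p_valid)
  dl <- -0.0078 * P^2 + (0.3 + work / 833) * P + 76 + work / 6
  pmax(dl, floor_value)
}

#' One implicit airway-compartment update
#'
#' Backward-Euler step of the well-mixed airway mass balance
#' `V dC/dt = flow * (C_in - C)` (wall uptake neglected for the respiratory
#' gases): `C_new = (C + r C_in) / (1 + r)`, `r = flow*dt/V`. Unconditionally
#' stable and bounded between `C` and `C_in`.
#'
#' @param C Current compartment concentration, ml gas / ml.
#' @param C_in Inlet concentration (parent on inhale, daughter on exhale).
#' @param flow Volumetric flow through the compartment, ml/s (>= 0).
#' @param V Compartment volume, ml (> 0).
#' @param dt Time step, s (> 0).
#' @return Updated concentration.
#' @export
airway_step <- function(C, C_in, flow, V, dt) {
  if (any(C < 0) || any(C_in < 0))
    stop_invalid("airway concentrations must be non-negative")
  if (dt <= 0 || any(flow < 0) || any(V <= 0))
    stop_invalid("require dt > 0, flow >= 0, V > 0")
  r <- flow * dt / V
  (C + r * C_in) / (1 + r)
}

#' One alveolar-compartment update
#'
#' Variable-volume alveolar mass balance. On inhale the compartment gains
#' airway gas by advection and changes volume by `+flow*dt`; on exhale the
#' volume falls by `flow*dt` and the concentration changes only through
#' membrane diffusion. Diffusive flux to the capillary is
#' `f_i * D_L * (P_Alv - P_c)` with `P_Alv = C_Alv * RT`.
#'
#' @param alv List with `C` (ml/ml) and `V` (ml).
#' @param phase `"inhale"` or `"exhale"`.
#' @param C_aw Feeding airway concentration (used on inhale).
#' @param flow Alveolar flow magnitude, ml/s (>= 0).
#' @param P_c Capillary partial pressure seen by the membrane, mmHg.
#' @param D_L Segment diffusing capacity `f_i * D_L`, ml/(mmHg*min).
#' @param dt Time step, s.
#' @param v_floor Residual volume floor, ml.
#' @return List with updated `C`, `V`, and `transfer` (ml gas moved to blood
#'   during the step).
#' @export
alveolar_step <- function(alv, phase = c("inhale", "exhale"), C_aw = 0,
                          flow = 0, P_c = 0, D_L = 0, dt = 0.01,
                          v_floor = 1) {
  phase <- match.arg(phase)
  if (dt <= 0 || flow < 0) stop_invalid("require dt > 0 and flow >= 0")
  V0 <- alv$V; C0 <- alv$C
  if (phase == "inhale") {
    V1 <- V0 + flow * dt
    M <- C0 * V0 + flow * dt * C_aw
  } else {
    V1 <- V0 - flow * dt
    if (V1 < v_floor)
      stop("alveolar volume underflow: exhalation past residual volume",
           call. = FALSE)
    M <- C0 * V1  # exhaled gas leaves at the compartment concentration
  }
  C_star <- M / V1
  # implicit diffusion against fixed P_c: V dC/dt = -DL/60 * (C*RT - P_c)
  k <- (D_L / 60) * dt / V1
  C1 <- (C_star + k * P_c) / (1 + k * PDM_RT)
  transfer <- (D_L / 60) * (C1 * PDM_RT - P_c) * dt
  list(C = C1, V = V1, transfer = transfer)
}

#' Build a serial capillary train
#'
#' The capillary bed of one segment is one tube discretized into `n` serial
#' well-mixed divisions of equal volume `V_capillary * f_k / n`, perfused at
#' `Q_c = Q_Tot * f_Qk` and exchanging with the alveolus at per-division
#' diffusing capacity `f_k * D_L / n`.
#'
#' @param n Number of serial divisions (>= 1).
#' @param V_capillary Whole-lung capillary volume, ml.
#' @param f_k Segment volume fraction.
#' @param Q_c Capillary blood flow through the train, ml/min.
#' @param P_init Initial blood partial pressure in every division, mmHg.
#' @param gas `"O2"` or `"CO2"`.
#' @param chem A [blood_chemistry()].
#' @return A `capillary_train` list with per-division `P` and `C`.
#' @export
capillary_train <- function(n = 10, V_capillary = 75, f_k = 1, Q_c = 5000,
                            P_init = 40, gas = "O2",
                            chem = blood_chemistry()) {
  stopifnot(n >= 1, V_capillary > 0, f_k > 0, Q_c > 0)
  P <- rep(P_init, n)
  C <- if (gas == "O2") o2_content(P, chem) else co2_content(P, chem)
  structure(list(n = as.integer(n), P = P, C = C,
                 V_div = V_capillary * f_k / n, Q_c = Q_c,
                 f_k = f_k, gas = gas, chem = chem),
            class = "capillary_train")
}

#' One implicit sweep of a capillary train
#'
#' Backward-Euler update of the serial capillary divisions from inlet to
#' outlet. Each division solves
#' `V_div (C' - C)/dt = Q_c/60 (C_in' - C') + (D_L/n)/60 (P_Alv - P(C'))`
#' for its end-of-step content `C'`; the nonlinear pressure-content relation
#' is handled by Newton iteration on pressure (closed form when the chemistry
#' is linear). The outlet division's content is the end-capillary value.
#'
#' @param train A [capillary_train()].
#' @param inlet_content Mixed-venous inflow content, ml/ml.
#' @param P_Alv Alveolar partial pressure, mmHg (held fixed over the step).
#' @param D_L_effective Segment diffusing capacity `f_k * D_L` after any
#'   damage reduction, ml/(mmHg*min) (for the whole train; divided by `n`
#'   per division).
#' @param dt Time step, s.
#' @return The updated train, with attribute `transfer` = total gas volume
#'   (ml) moved from alveolus to blood during the step.
#' @export
capillary_step <- function(train, inlet_content, P_Alv, D_L_effective, dt) {
  stopifnot(inherits(train, "capillary_train"), dt > 0)
  if (inlet_content < 0) stop_invalid("inlet content must be non-negative")
  chem <- train$chem
  q <- train$Q_c / 60                         # ml/s
  g <- (D_L_effective / train$n) / 60         # ml/(mmHg*s) per division
  V <- train$V_div
  C_in <- inlet_content
  transfer <- 0
  for (i in seq_len(train$n)) {
    C0 <- train$C[i]
    a <- q * dt / V
    b <- g * dt / V
    if (chem$linear) {
      beta <- chem$beta_linear
      C1 <- (C0 + a * C_in + b * P_Alv) / (1 + a + b / beta)
      P1 <- C1 / beta
    } else {
      # Newton on P1: F(P) = C(P) (1+a) - C0 - a C_in - b (P_Alv - P) = 0
      cfun <- if (train$gas == "O2") o2_content else co2_content
      dC <- function(p) {
        if (train$gas == "CO2") return(chem$co2_slope)
        n_h <- chem$hill_n; P50 <- chem$P50
        cap <- chem$o2_capacity * chem$Hb / 100
        s <- p^n_h / (p^n_h + P50^n_h)
        ds <- if (p > 0) n_h * s * (1 - s) / p else 0
        cap * ds + chem$beta_O2
      }
      P1 <- max(train$P[i], 1e-6)
      for (it in 1:50) {
        Fv <- cfun(P1, chem) * (1 + a) - C0 - a * C_in - b * (P_Alv - P1)
        dF <- dC(P1) * (1 + a) + b
        step <- Fv / dF
        P1 <- P1 - step
        if (P1 < 0) P1 <- P1 + step - (P1 - step) / 2  # bisect toward 0
        if (abs(step) < 1e-10) break
      }
      if (!is.finite(P1) || it == 50 && abs(step) > 1e-6)
        stop("capillary dissociation-curve inversion failed in division ", i,
             call. = FALSE)
      C1 <- cfun(P1, chem)
    }
    transfer <- transfer + g * (P_Alv - P1) * dt
    train$C[i] <- C1
    train$P[i] <- P1
    C_in <- C1
  }
  attr(train, "transfer") <- transfer
  train
}

#' Closed-form steady state of a capillary train under linear chemistry
#'
#' With `content = beta * P`, constant alveolar pressure and constant inlet,
#' the steady state of each division obeys the geometric recursion
#' `C_i = (C_{i-1} + a beta P_Alv) / (1 + a)`, `a = f_k D_L / (n Q_c beta)`
#' (flows in consistent units). Used as an analytic oracle for the implicit
#' sweep.
#'
#' @inheritParams capillary_step
#' @return Numeric vector of steady-state division contents.
#' @export
capillary_steady_linear <- function(train, inlet_content, P_Alv, D_L_effective) {
  stopifnot(train$chem$linear)
  beta <- train$chem$beta_linear
  a <- (D_L_effective / train$n) / (train$Q_c * beta)
  C <- numeric(train$n)
  prev <- inlet_content
  for (i in seq_len(train$n)) {
    C[i] <- (prev + a * beta * P_Alv) / (1 + a)
    prev <- C[i]
  }
  C
}

#' Arterial mixing of end-capillary blood with shunted venous blood
#'
#' `C_a = (1 - shunt) * sum(f_Qk C_k) / sum(f_Qk) + shunt * C_v`.
#'
#' @param end_capillary Per-segment end-capillary contents, ml/ml.
#' @param flows Per-segment perfusion weights (fractions or flows).
#' @param venous_content Mixed-venous content, ml/ml.
#' @param shunt Shunt fraction of cardiac output in \[0, 1\].
#' @return Arterial content, ml/ml.
#' @export
mix_arterial <- function(end_capillary, flows, venous_content, shunt) {
  if (length(end_capillary) != length(flows))
    stop_invalid("end-capillary contents and flows must have equal length")
  if (!is.finite(shunt) || shunt < 0 || shunt > 1)
    stop_invalid("shunt must lie in [0, 1]")
  if (sum(flows) <= 0) stop_invalid("flows must have positive sum")
  (1 - shunt) * sum(flows * end_capillary) / sum(flows) +
    shunt * venous_content
}
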