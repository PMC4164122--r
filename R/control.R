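# Whole-body closure: ventilatory control, breathing pattern, metabolic
# demand, cardiac output and the oxygen-deficit fatigue endpoint. The control
# laws are the package's own re-creation of a standard chemoreflex + exercise
# drive; every gain is a configuration parameter with defaults tuned to the
# resting sanity envelope (P_a_O2 85-105 mmHg, P_a_CO2 35-45 mmHg,
# VE 5-8 L/min).

#' Default ventilatory-control parameters
#'
#' @param VE_rest Resting minute ventilation, L/min.
#' @param G_CO2 Central CO2 gain, L/min per mmHg above the setpoint.
#' @param B_CO2 Arterial CO2 setpoint, mmHg.
#' @param G_hyp Hypoxic gain, L/min per unit of saturation below `S_ref`.
#' @param S_ref Saturation threshold for the hypoxic drive.
#' @param k_ex Exercise drive, L/min per W.
#' @param tau_up,tau_down First-order time constants (s) for rising and
#'   falling ventilation.
#' @param G_phasic Gain of the phasic (adapting) hypoxic component, L/min per
#'   unit of un-adapted saturation drive; responsible for the transient
#'   ventilation overshoot on a hypoxic step.
#' @param tau_adapt Adaptation time constant of the phasic component, s.
#' @param VT_rest Resting tidal volume, ml.
#' @param VT_slope Tidal-volume increase per L/min of ventilation above rest,
#'   ml/(L/min).
#' @param VT_cap Tidal-volume ceiling (ml); further ventilation increases are
#'   carried by frequency.
#' @param insp_fraction Fraction of the breathing cycle spent in inspiration.
#' @return Named list of control parameters.
#' @export
control_params <- function(VE_rest = 6, G_CO2 = 2, B_CO2 = 40,
                           G_hyp = 100, S_ref = 0.94, k_ex = 0.25,
                           G_phasic = 60, tau_adapt = 90,
                           tau_up = 15, tau_down = 40,
                           VT_rest = 500, VT_slope = 50, VT_cap = 3000,
                           insp_fraction = 0.35) {
  as.list(environment())
}

#' Scale ventilatory-control parameters to body mass
#'
#' Volume-like controller parameters (resting ventilation, tidal volumes and
#' the ventilation gains) scale linearly with body mass from the 70 kg human
#' reference; the exercise drive per watt and the time constants do not.
#'
#' @param params A [control_params()] list.
#' @param body_mass kg.
#' @param reference_mass kg; mass at which the defaults apply.
#' @return The rescaled parameter list.
#' @export
scale_control_params <- function(params, body_mass, reference_mass = 70) {
  r <- body_mass / reference_mass
  for (nm in c("VE_rest", "VT_rest", "VT_cap", "G_CO2", "G_hyp", "G_phasic"))
    params[[nm]] <- params[[nm]] * r
  params
}

#' Target minute ventilation from chemical and exercise drives
#'
#' `VE = VE_rest + G_CO2 max(0, P_a_CO2 - B) + G_hyp max(0, S_ref - SaO2)
#'  + G_phasic phasic + k_ex work`. The saturating `max(0, .)` terms make the
#' drive well defined for any physiologic input. The phasic term is the
#' un-adapted part of the hypoxic drive — the controller responds to recent
#' *changes* in saturation more strongly than to a sustained level — and is
#' maintained by the scenario loop ([run_scenario()]): it rises immediately
#' with a desaturation step and fades with time constant `tau_adapt`,
#' producing the ventilation overshoot followed by exponential decay to a
#' plateau on a hypoxic step. At rest and at any steady state it is zero.
#'
#' @param SaO2 Arterial O2 saturation fraction.
#' @param P_a_CO2 Arterial CO2 pressure, mmHg.
#' @param work Exercise load, W.
#' @param params A [control_params()] list.
#' @param phasic Un-adapted hypoxic drive (saturation units); 0 at steady
#'   state.
#' @return Target VE, L/min.
#' @export
ventilatory_drive <- function(SaO2, P_a_CO2, work = 0,
                              params = control_params(), phasic = 0) {
  params$VE_rest +
    params$G_CO2 * max(0, P_a_CO2 - params$B_CO2) +
    params$G_hyp * max(0, params$S_ref - SaO2) +
    params$G_phasic * max(0, phasic) +
    params$k_ex * work
}

#' Split minute ventilation into tidal volume and frequency
#'
#' Tidal volume rises linearly with ventilation above rest
#' (`VT = VT_rest + VT_slope * (VE - VE_rest)`) up to a ceiling, after which
#' breathing frequency carries further increases; `VT * Freq = VE` always.
#' Both outputs are monotone non-decreasing in VE. The inspiratory time
#' fraction is fixed at 35% of the cycle.
#'
#' @param VE Minute ventilation, L/min (> 0).
#' @param params A [control_params()] list.
#' @return List with `V_T` (ml), `Freq` (breaths/min) and `insp_fraction`.
#' @export
breathing_pattern <- function(VE, params = control_params()) {
  if (!is.finite(VE) || VE <= 0) stop_invalid("VE must be positive")
  V_T <- params$VT_rest + params$VT_slope * max(0, VE - params$VE_rest)
  V_T <- min(V_T, params$VT_cap)
  Freq <- VE * 1000 / V_T
  list(V_T = V_T, Freq = Freq, insp_fraction = params$insp_fraction)
}

#' Default metabolic parameters
#'
#' @param VO2_rest Resting oxygen consumption at 70 kg, L/min.
#' @param k_O2 Oxygen cost of external work, L/min per W.
#' @param RQ Respiratory quotient VCO2/VO2.
#' @param Q_rest Resting cardiac output at 70 kg, L/min.
#' @param k_Q Cardiac-output gain, L blood per L O2 consumed.
#' @param Q_max Maximal cardiac output at 70 kg, L/min (linear in mass);
#'   caps oxygen delivery at heavy exercise.
#' @param reference_mass Mass (kg) at which the resting terms apply; they
#'   scale linearly with body mass.
#' @return Named list.
#' @export
metabolic_params <- function(VO2_rest = 0.3, k_O2 = 0.0116, RQ = 0.85,
                             Q_rest = 5, k_Q = 5, Q_max = 25,
                             reference_mass = 70) {
  as.list(environment())
}

#' Metabolic demand from workload
#'
#' `VO2 = VO2_rest + k_O2 * work`, `VCO2 = RQ * VO2`. Resting consumption
#' scales linearly with body mass from the 70 kg reference.
#'
#' @param work Exercise load, W (>= 0).
#' @param params A [metabolic_params()] list.
#' @param body_mass Body mass, kg.
#' @return List with `VO2` and `VCO2`, L/min STPD.
#' @export
metabolic_demand <- function(work, params = metabolic_params(),
                             body_mass = params$reference_mass) {
  if (any(work < 0)) stop_invalid("work must be non-negative")
  VO2 <- params$VO2_rest * body_mass / params$reference_mass +
    params$k_O2 * work
  list(VO2 = VO2, VCO2 = params$RQ * VO2)
}

#' Cardiac output from oxygen consumption
#'
#' `Q_Tot = min(Q_rest + k_Q * VO2, Q_max)`, with the resting term and the
#' ceiling scaled linearly with body mass.
#'
#' @inheritParams metabolic_demand
#' @param VO2 Oxygen consumption, L/min.
#' @return Cardiac output, L/min.
#' @export
cardiac_output <- function(VO2, params = metabolic_params(),
                           body_mass = params$reference_mass) {
  r <- body_mass / params$reference_mass
  min(params$Q_rest * r + params$k_Q * VO2, params$Q_max * r)
}

#' Default fatigue parameters
#'
#' Fatigue is modelled as an oxygen deficit accumulator: whenever oxygen
#' delivery falls short of demand the deficit grows; fatigue (inability to
#' hold the target workload) is declared when the deficit exceeds capacity.
#'
#' @param D_max Deficit capacity at 70 kg, ml O2; scales linearly with mass.
#' @param C_floor Minimum venous O2 content tissue extraction can reach,
#'   ml/ml.
#' @param reference_mass Reference mass, kg.
#' @return Named list.
#' @export
fatigue_params <- function(D_max = 2500, C_floor = 0.02,
                           reference_mass = 70) {
  list(D_max = D_max, C_floor = C_floor, reference_mass = reference_mass)
}

#' Advance the oxygen-deficit fatigue accumulator
#'
#' Delivered oxygen is limited by perfusion and arterial content:
#' `VO2_delivered = min(demand, Q_Tot * (C_a_O2 - C_floor))`; the deficit
#' grows at `max(0, demand - delivered)` and never decreases below zero.
#'
#' @param deficit Current deficit, ml O2.
#' @param VO2_demand Demanded oxygen uptake, ml/min STPD.
#' @param Q_Tot Cardiac output, ml/min.
#' @param C_a_O2 Arterial O2 content, ml/ml.
#' @param dt Time step, s (> 0).
#' @param params A [fatigue_params()] list.
#' @return List with updated `deficit` (ml), `VO2_delivered` (ml/min) and
#'   logical `fatigued` (deficit above capacity, scaled to `body_mass`).
#' @export
fatigue_update <- function(deficit, VO2_demand, Q_Tot, C_a_O2, dt,
                           params = fatigue_params(),
                           body_mass = params$reference_mass) {
  if (dt <= 0) stop_invalid("dt must be positive")
  supply_max <- Q_Tot * max(0, C_a_O2 - params$C_floor)
  delivered <- min(VO2_demand, supply_max)
  deficit <- max(0, deficit + (VO2_demand - delivered) * dt / 60)
  D_max <- params$D_max * body_mass / params$reference_mass
  list(deficit = deficit, VO2_delivered = delivered,
       fatigued = deficit > D_max)
}

#' Treadmill speed/grade to mechanical workload
#'
#' Locomotion cost model `W = mass * speed * (c_level + g * grade/100)` with
#' `g = 9.81`; `c_level` is the level-running cost coefficient
#' (W per kg per m/s), exposed in configuration.
#'
#' @param speed m/s.
#' @param grade Percent grade.
#' @param body_mass kg.
#' @param c_level Level locomotion coefficient, W/(kg*m/s).
#' @return Workload in W.
#' @export
treadmill_work <- function(speed, grade = 0, body_mass = 70, c_level = 1.5) {
  body_mass * speed * (c_level + 9.81 * grade / 100)
}

#' The ramped treadmill protocol used for fatigue runs
#'
#' Speed starts at 0.67 m/s and increases by 0.22 m/s every 90 s until capped
#' at 2.22 m/s, at 9% grade.
#'
#' @param t Time from run start, s. Vectorized.
#' @return Speed in m/s.
#' @export
sheep_ramp_speed <- function(t) {
  pmin(0.67 + 0.22 * floor(t / 90), 2.22)
}
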