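# Breath-by-breath time-stepping engine: couples the anatomy, distribution,
# gas-transport, damage and control modules. The inner loop (implicit airway
# and capillary sweeps, alveolar mass balance, arterial mixing) is compiled;
# the per-breath controller updates run in R.

#' Solver settings
#'
#' @param dt Inner time step, s.
#' @param n_div Serial capillary divisions per segment.
#' @param max_breaths Breath limit for steady-state searches.
#' @param ss_tol Steady-state criterion: relative change per breath in
#'   arterial O2 and CO2 pressure, required for `ss_consecutive` breaths.
#' @param ss_consecutive Consecutive converged breaths required.
#' @param V_ven Well-mixed venous/tissue pool volume at 70 kg, ml; scales
#'   linearly with body mass.
#' @param dl_floor Floor on the workload-dependent O2 diffusing capacity,
#'   ml/(mmHg*min).
#' @return Named list of solver settings.
#' @export
solver_settings <- function(dt = 0.01, n_div = 10, max_breaths = 200,
                            ss_tol = 1e-3, ss_consecutive = 5,
                            V_ven = 3000, dl_floor = 1) {
  as.list(environment())
}

#' Environment description
#'
#' @param FiO2,FiCO2 Inspired dry-gas fractions.
#' @param P_B Barometric pressure, mmHg.
#' @return Named list.
#' @export
environment_air <- function(FiO2 = 0.2093, FiCO2 = 0, P_B = 760) {
  if (FiO2 < 0 || FiCO2 < 0 || FiO2 + FiCO2 > 1 || P_B <= 0)
    stop_invalid("invalid environment: need FiO2, FiCO2 >= 0, sum <= 1, P_B > 0")
  list(FiO2 = FiO2, FiCO2 = FiCO2, P_B = P_B)
}

# Inspired (tracheal, humidified) concentrations, ml STPD / ml.
inspired_concentration <- function(env) {
  c(O2 = env$FiO2 * (env$P_B - 47) / PDM_RT,
    CO2 = env$FiCO2 * (env$P_B - 47) / PDM_RT)
}

# Precompile model topology into the 0-based index arrays the engine expects.
compile_topology <- function(model, fractions, n_div) {
  ids <- model$airways$id
  idx <- function(id) match(id, ids) - 1L
  parent <- ifelse(is.na(model$parent), -1L, idx(model$parent))
  # topological order root-first
  depth <- airway_depths(model)
  order0 <- order(depth) - 1L
  seg <- model$segments
  seg_leaf <- idx(seg$feeding_airway_id)
  # subtended ventilation fraction per airway compartment
  fV <- fractions$ventilation
  aw_frac <- numeric(length(ids))
  for (k in seq_len(nrow(seg))) {
    j <- seg_leaf[k] + 1L
    repeat {
      aw_frac[j] <- aw_frac[j] + fV[k]
      p <- parent[j]
      if (p < 0) break
      j <- p + 1L
    }
  }
  list(aw_parent = as.integer(parent),
       order = as.integer(order0),
       aw_vol = model$airways$volume_ml,
       aw_frac = aw_frac,
       seg_leaf = as.integer(seg_leaf),
       ds_vol = pmax(seg$deadspace_ml, 0.5),
       f = seg$f,
       fV = fV,
       fQ = fractions$perfusion,
       alv_floor = 0.1 * seg$alv_volume_ml,
       n_div = as.integer(n_div))
}

#' Initialize the whole-body physiologic state
#'
#' Gas stores start near a normal resting operating point (alveolar O2
#' ~100 mmHg, CO2 ~40 mmHg; venous O2 ~40 mmHg, CO2 ~46 mmHg) so closed-loop
#' runs settle within a few tens of breaths.
#'
#' @param model A `lung_model`.
#' @param env An [environment_air()] list.
#' @param chem A [blood_chemistry()].
#' @param settings A [solver_settings()] list.
#' @param control A [control_params()] list.
#' @return An object of class `physio_state`.
#' @export
init_physio <- function(model, env = environment_air(),
                        chem = blood_chemistry(),
                        settings = solver_settings(),
                        control = control_params()) {
  n_seg <- nrow(model$segments)
  n_aw <- nrow(model$airways)
  C_ins <- inspired_concentration(env)
  alv_C <- cbind(rep(100 / PDM_RT, n_seg), rep(40 / PDM_RT, n_seg))
  aw_C <- cbind(rep(C_ins[1], n_aw), rep(C_ins[2], n_aw))
  ds_C <- cbind(rep((C_ins[1] + 100 / PDM_RT) / 2, n_seg), rep(40 / PDM_RT, n_seg))
  cap_P <- array(0, dim = c(n_seg, settings$n_div, 2))
  cap_P[, , 1] <- 95
  cap_P[, , 2] <- 41
  C_ven <- c(o2_content(40, chem), co2_content(46, chem))
  pat <- breathing_pattern(control$VE_rest, control)
  structure(list(
    engine = list(aw_C = aw_C, ds_C = ds_C, alv_C = alv_C,
                  alv_V = model$segments$alv_volume_ml,
                  cap_P = as.numeric(cap_P), C_ven = C_ven),
    VE = control$VE_rest, V_T = pat$V_T, Freq = pat$Freq,
    Q_Tot = NA_real_, VO2 = NA_real_, VCO2 = NA_real_,
    C_art = c(o2_content(95, chem), co2_content(40, chem)),
    P_a_O2 = 95, P_a_CO2 = 40, SaO2 = o2_saturation(95, chem),
    deficit = 0, time = 0
  ), class = "physio_state")
}

#' @export
print.physio_state <- function(x, ...) {
  cat(sprintf(
    "Physiologic state at t = %.1f s:\n  VE %.2f L/min (VT %.0f ml, f %.1f /min), P_a_O2 %.1f mmHg, P_a_CO2 %.1f mmHg, SaO2 %.3f\n",
    x$time, x$VE, x$V_T, x$Freq, x$P_a_O2, x$P_a_CO2, x$SaO2))
  if (is.finite(x$Q_Tot))
    cat(sprintf("  Q_Tot %.2f L/min, VO2 %.2f L/min, deficit %.0f ml O2\n",
                x$Q_Tot / 1000, x$VO2 / 1000, x$deficit))
  invisible(x)
}

#' Advance the model through one breath
#'
#' Runs one full inspiration (35% of the cycle by default) and expiration
#' through the compiled engine: implicit airway sweeps root-to-leaf on inhale
#' and leaf-to-root on exhale, alveolar mass balance, serial capillary
#' uptake with the workload-dependent O2 diffusing capacity, shunt mixing and
#' venous-pool update.
#'
#' @param model A `lung_model`.
#' @param physio A `physio_state` from [init_physio()].
#' @param damage A `damage_state` (default healthy).
#' @param settings A [solver_settings()] list.
#' @param env An [environment_air()] list.
#' @param chem A [blood_chemistry()].
#' @param work Workload, W (enters the O2 diffusing-capacity relation).
#' @param V_T,Freq Tidal volume (ml) and frequency (/min); default from the
#'   state.
#' @param Q_Tot Cardiac output, ml/min.
#' @param VO2,VCO2 Tissue O2 consumption and CO2 production, ml/min STPD.
#' @param insp_fraction Inspiratory fraction of the cycle.
#' @param dl_fixed_o2 If positive, use this constant O2 diffusing capacity
#'   (ml/(mmHg*min)) instead of the workload-dependent relation (fixtures and
#'   analytic oracles).
#' @param clamp_venous If `TRUE` the venous pool is held fixed (open-loop
#'   oracle runs).
#' @param C_floor Minimum venous O2 content for extraction, ml/ml.
#' @param fractions Optional precomputed [flow_fractions()].
#' @return The updated `physio_state`; the engine diagnostics (per-breath gas
#'   uptake, inspired/expired volumes, mass-balance residual) are attached as
#'   attribute `"diag"`.
#' @export
run_breath <- function(model, physio, damage = healthy_damage(model),
                       settings = solver_settings(), env = environment_air(),
                       chem = blood_chemistry(), work = 0,
                       V_T = physio$V_T, Freq = physio$Freq,
                       Q_Tot = 6500, VO2 = 300, VCO2 = 255,
                       insp_fraction = 0.35, dl_fixed_o2 = 0,
                       clamp_venous = FALSE, C_floor = 0.02,
                       fractions = NULL) {
  stopifnot(inherits(model, "lung_model"), inherits(physio, "physio_state"))
  if (is.null(fractions)) fractions <- flow_fractions(model)
  topo <- compile_topology(model, fractions, settings$n_div)
  dl_scale <- model$D_L_O2_ref / PDM_DEFAULTS$D_L_O2_ref
  pars <- list(dt = settings$dt, V_T = V_T, Freq = Freq,
               insp_fraction = insp_fraction,
               C_insp = unname(inspired_concentration(env)),
               Q_Tot = Q_Tot, shunt = damage$shunt,
               dl_red = damage$dl_reduction, D_L_CO2 = model$D_L_CO2,
               work = work, dl_floor = settings$dl_floor,
               dl_fixed_o2 = dl_fixed_o2, dl_scale = dl_scale,
               VO2 = VO2, VCO2 = VCO2,
               V_ven = settings$V_ven * model$body_mass / 70,
               C_floor = C_floor, V_capillary = model$V_capillary,
               n_div = settings$n_div, RT = PDM_RT, clamp_venous = clamp_venous,
               chem = unclass(chem))
  out <- engine_run_breath(topo, physio$engine, pars)
  physio$engine <- out[c("aw_C", "ds_C", "alv_C", "alv_V", "cap_P", "C_ven")]
  physio$C_art <- out$C_art
  physio$P_a_O2 <- content_to_pressure(out$C_art[1], "O2", chem)
  physio$P_a_CO2 <- content_to_pressure(out$C_art[2], "CO2", chem)
  physio$SaO2 <- o2_saturation(physio$P_a_O2, chem)
  physio$V_T <- V_T; physio$Freq <- Freq
  physio$VE <- V_T * Freq / 1000
  physio$Q_Tot <- Q_Tot; physio$VO2 <- VO2; physio$VCO2 <- VCO2
  physio$time <- physio$time + out$T_breath
  attr(physio, "diag") <- out[c("uptake", "inspired", "expired", "residual",
                                "vo2_delivered_ml", "C_art_mean", "alv_P_O2",
                                "T_breath")]
  physio
}

#' Closed-loop steady state under constant conditions
#'
#' Runs the full closed loop (ventilatory control, metabolic demand, cardiac
#' output, gas exchange) at a constant workload and environment until the
#' arterial O2 and CO2 pressures change by less than `ss_tol` (relative) per
#' breath for `ss_consecutive` consecutive breaths.
#'
#' @param model A `lung_model`.
#' @param work Constant workload, W.
#' @param env An [environment_air()] list.
#' @param damage A `damage_state`.
#' @param control,metab,blood,solver Parameter lists (see
#'   [control_params()], [metabolic_params()], [blood_chemistry()],
#'   [solver_settings()]); entries override the defaults.
#' @return List of converged values: `VE`, `V_T`, `Freq`, `Q_Tot` (L/min),
#'   `VO2`, `VCO2` (L/min), `P_a_O2`, `P_a_CO2` (mmHg), `SaO2`, `C_a_O2`
#'   (ml/ml), `breaths` used.
#' @export
steady_state <- function(model, work = 0, env = environment_air(),
                         damage = healthy_damage(model),
                         control = list(), metab = list(), blood = list(),
                         solver = list()) {
  cp <- scale_control_params(utils::modifyList(control_params(), control),
                             model$body_mass)
  mp <- utils::modifyList(metabolic_params(), metab)
  chem <- do.call(blood_chemistry, blood)
  st <- utils::modifyList(solver_settings(), solver)
  fractions <- flow_fractions(model)
  physio <- init_physio(model, env, chem, st, cp)
  dem <- metabolic_demand(work, mp, model$body_mass)
  Q <- cardiac_output(dem$VO2, mp, model$body_mass) * 1000
  ok <- 0L; prev <- c(physio$P_a_O2, physio$P_a_CO2)
  for (b in seq_len(st$max_breaths)) {
    target <- ventilatory_drive(physio$SaO2, physio$P_a_CO2, work, cp)
    tau <- if (target > physio$VE) cp$tau_up else cp$tau_down
    T_prev <- 60 / physio$Freq
    VE <- target + (physio$VE - target) * exp(-T_prev / tau)
    pat <- breathing_pattern(VE, cp)
    physio <- run_breath(model, physio, damage, st, env, chem, work,
                         V_T = pat$V_T, Freq = pat$Freq, Q_Tot = Q,
                         VO2 = dem$VO2 * 1000, VCO2 = dem$VCO2 * 1000,
                         insp_fraction = cp$insp_fraction,
                         fractions = fractions)
    cur <- c(physio$P_a_O2, physio$P_a_CO2)
    ok <- if (all(abs(cur - prev) / pmax(abs(prev), 1) < st$ss_tol)) ok + 1L else 0L
    prev <- cur
    if (ok >= st$ss_consecutive) {
      return(list(VE = physio$VE, V_T = physio$V_T, Freq = physio$Freq,
                  Q_Tot = Q / 1000, VO2 = dem$VO2, VCO2 = dem$VCO2,
                  P_a_O2 = physio$P_a_O2, P_a_CO2 = physio$P_a_CO2,
                  SaO2 = physio$SaO2, C_a_O2 = physio$C_art[1],
                  breaths = b, state = physio))
    }
  }
  stop("steady state not reached within ", st$max_breaths, " breaths",
       call. = FALSE)
}

#' Execute a scenario
#'
#' Runs the closed-loop model through a scenario configuration: an
#' environment and workload timeline, an optional damage pattern, optional
#' isocapnic clamping, and the fatigue accumulator. Once the oxygen deficit
#' exceeds capacity the delivered (sustainable) power is reported in the
#' `power_out` channel, which deviates from the target workload — the first
#' such breath defines the time to fatigue.
#'
#' @param config A `scenario_config` from [load_config()] /
#'   [scenario_config()], or a preset name (see [list_presets()]).
#' @return A `dpm_timeseries`: data frame of breath-resolution channels with
#'   the configuration and summary (`time_to_fatigue_s`, final state) as
#'   attributes.
#' @export
run_scenario <- function(config) {
  if (is.character(config)) config <- load_preset(config)
  stopifnot(inherits(config, "scenario_config"))
  cp <- scale_control_params(do.call(control_params, config$control),
                             config$body_mass)
  mp <- do.call(metabolic_params, config$metabolism)
  fp <- do.call(fatigue_params, config$fatigue)
  chem <- do.call(blood_chemistry, config$blood)
  st <- do.call(solver_settings, config$solver)
  model <- switch(config$species,
                  human = build_human_lung(config$body_mass),
                  sheep = build_sheep_lung(config$body_mass),
                  goat = build_goat_lung(config$body_mass))
  damage <- config_damage(model, config)
  fractions <- flow_fractions(model)
  physio <- init_physio(model, environment_at(config, 0), chem, st, cp)

  rows <- list(); t <- 0; fat_time <- NA_real_
  fic_extra <- 0; p_co2_ref <- NA_real_
  hyp_adapted <- 0  # adaptation state of the phasic hypoxic drive
  i <- 0L
  while (t < config$duration_s) {
    i <- i + 1L
    env <- environment_at(config, t)
    work <- workload_at(config, t, mp)
    if (isTRUE(config$isocapnic)) {
      if (is.na(p_co2_ref)) p_co2_ref <- physio$P_a_CO2
      fic_extra <- max(0, fic_extra + 0.005 * (p_co2_ref - physio$P_a_CO2))
      env$FiCO2 <- min(env$FiCO2 + fic_extra, 1 - env$FiO2)
    }
    dem <- metabolic_demand(work, mp, model$body_mass)
    Q <- cardiac_output(dem$VO2, mp, model$body_mass) * 1000
    hyp_drive <- max(0, cp$S_ref - physio$SaO2)
    T_prev <- 60 / physio$Freq
    hyp_adapted <- hyp_adapted +
      (hyp_drive - hyp_adapted) * (1 - exp(-T_prev / cp$tau_adapt))
    target <- ventilatory_drive(physio$SaO2, physio$P_a_CO2, work, cp,
                                phasic = hyp_drive - hyp_adapted)
    tau <- if (target > physio$VE) cp$tau_up else cp$tau_down
    VE <- target + (physio$VE - target) * exp(-60 / physio$Freq / tau)
    pat <- breathing_pattern(VE, cp)
    physio <- run_breath(model, physio, damage, st, env, chem, work,
                         V_T = pat$V_T, Freq = pat$Freq, Q_Tot = Q,
                         VO2 = dem$VO2 * 1000, VCO2 = dem$VCO2 * 1000,
                         insp_fraction = cp$insp_fraction, C_floor = fp$C_floor,
                         fractions = fractions)
    dg <- attr(physio, "diag")
    fu <- fatigue_update(physio$deficit, dem$VO2 * 1000, Q, physio$C_art[1],
                         dg$T_breath, fp, model$body_mass)
    physio$deficit <- fu$deficit
    power_out <- if (fu$fatigued) {
      if (is.na(fat_time)) fat_time <- t
      max(0, (fu$VO2_delivered / 1000 -
                mp$VO2_rest * model$body_mass / mp$reference_mass) / mp$k_O2)
    } else work
    t <- t + dg$T_breath
    rows[[i]] <- data.frame(
      time_s = t, VE = physio$VE, V_T = physio$V_T, Freq = physio$Freq,
      SaO2 = physio$SaO2, P_a_O2 = physio$P_a_O2, P_a_CO2 = physio$P_a_CO2,
      C_a_O2 = physio$C_art[1], C_v_O2 = physio$engine$C_ven[1],
      Q_Tot = Q / 1000, VO2_demand = dem$VO2,
      VO2_delivered = fu$VO2_delivered / 1000,
      uptake_O2_ml = dg$uptake[1], work_target = work, power_out = power_out,
      deficit_ml = physio$deficit, FiO2 = env$FiO2, FiCO2 = env$FiCO2)
  }
  ts <- do.call(rbind, rows)
  structure(ts, class = c("dpm_timeseries", "data.frame"),
            config = config, time_to_fatigue_s = fat_time,
            final_state = physio, fractions = fractions)
}

#' Time to fatigue for a scenario
#'
#' @param config Scenario configuration or preset name.
#' @return First time (s) at which the oxygen deficit exceeds capacity, or
#'   `Inf` if fatigue never occurs within the scenario duration.
#' @export
time_to_fatigue <- function(config) {
  ts <- run_scenario(config)
  ttf <- attr(ts, "time_to_fatigue_s")
  if (is.na(ttf)) Inf else ttf
}

#' @export
print.dpm_timeseries <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("DPM scenario time series: %s, %.0f s, %d breaths\n",
              if (is.null(cfg)) "unnamed" else cfg$name %||% "unnamed",
              max(x$time_s), nrow(x)))
  ttf <- attr(x, "time_to_fatigue_s") %||% NA_real_
  cat(sprintf("  time to fatigue: %s\n",
              if (is.na(ttf)) "none" else sprintf("%.0f s", ttf)))
  last <- x[nrow(x), ]
  cat(sprintf("  final: VE %.1f L/min, SaO2 %.3f, P_a_O2 %.1f, P_a_CO2 %.1f mmHg\n",
              last$VE, last$SaO2, last$P_a_O2, last$P_a_CO2))
  invisible(x)
}

#' @export
plot.dpm_timeseries <- function(x, channels = c("VE", "SaO2", "P_a_O2"), ...) {
  op <- graphics::par(mfrow = c(length(channels), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (ch in channels)
    graphics::plot(x$time_s, x[[ch]], type = "l", xlab = "time (s)",
                   ylab = ch, ...)
  invisible(x)
}

#' Write a scenario time series to CSV
#'
#' Writes a commented header block (scenario name, species, key parameters,
#' flow fractions) followed by the breath-resolution channels.
#'
#' @param ts A `dpm_timeseries`.
#' @param path Output file.
#' @param long If `TRUE`, write tidy long format (time_s, channel, value).
#' @export
write_timeseries_csv <- function(ts, path, long = FALSE) {
  cfg <- attr(ts, "config")
  fr <- attr(ts, "fractions")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pulmodpm scenario: %s", cfg$name %||% "unnamed"),
    sprintf("# species: %s, body_mass_kg: %g", cfg$species, cfg$body_mass),
    sprintf("# time_to_fatigue_s: %s",
            format(attr(ts, "time_to_fatigue_s"))),
    sprintf("# ventilation_fractions: %s",
            paste(signif(fr$ventilation, 4), collapse = ",")),
    sprintf("# perfusion_fractions: %s",
            paste(signif(fr$perfusion, 4), collapse = ","))), con)
  df <- as.data.frame(ts)
  if (long) {
    df <- data.frame(time_s = rep(df$time_s, ncol(df) - 1),
                     channel = rep(names(df)[-1], each = nrow(df)),
                     value = unlist(df[-1], use.names = FALSE))
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
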