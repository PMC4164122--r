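# Scenario configuration, presets, fixtures and synthetic calibration data.

PDM_CONFIG_KEYS <- c("schema_version", "name", "species", "body_mass",
                     "duration_s", "isocapnic", "environment", "workload",
                     "treadmill", "damage", "control", "metabolism",
                     "fatigue", "blood", "solver", "seed")

#' Construct and validate a scenario configuration
#'
#' The declarative description of a simulation: species and mass, an
#' environment timeline (inspired fractions and barometric pressure), a
#' workload timeline in watts or a treadmill protocol, an optional damage
#' pattern, and parameter blocks for the controller, metabolism, fatigue,
#' blood chemistry and solver. Unknown keys are rejected.
#'
#' @param species `"human"`, `"sheep"` or `"goat"`.
#' @param body_mass kg; defaults to the species reference mass.
#' @param duration_s Simulated duration, s.
#' @param environment List of timeline entries `list(t=, FiO2=, FiCO2=,
#'   P_B=)`; later entries inherit unspecified fields from earlier ones.
#' @param workload List of entries `list(t=, work=)` (W).
#' @param treadmill Optional list `list(protocol="sheep_ramp"| NULL,
#'   speed=, grade=, c_level=)`; overrides `workload`.
#' @param damage Optional list: `list(uniform = dW)`, `list(region =
#'   "right", dW = )`, `list(per_segment = list(id = dW, ...))` (all with
#'   optional `k_w`), or a direct pair `list(shunt = , dl_reduction = )`.
#' @param isocapnic Hold arterial CO2 at its pre-perturbation value via an
#'   inspired-CO2 controller.
#' @param control,metabolism,fatigue,blood,solver Named parameter overrides.
#' @param name Label for reports.
#' @param seed Integer; recorded for provenance (the simulator itself is
#'   deterministic).
#' @param schema_version Config schema version (must be 1).
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(species = "human", body_mass = NULL,
                            duration_s = 120,
                            environment = list(list(t = 0)),
                            workload = list(list(t = 0, work = 0)),
                            treadmill = NULL, damage = NULL,
                            isocapnic = FALSE,
                            control = list(), metabolism = list(),
                            fatigue = list(), blood = list(), solver = list(),
                            name = NULL, seed = 1L, schema_version = 1L) {
  if (schema_version != 1L) stop("unsupported config schema_version", call. = FALSE)
  species <- match.arg(species, c("human", "sheep", "goat"))
  if (is.null(body_mass)) body_mass <- PDM_REF_MASS[[species]]
  if (body_mass <= 0) stop_invalid("body_mass must be positive")
  if (duration_s <= 0) stop_invalid("duration_s must be positive")
  env_tl <- normalize_timeline(environment,
                               defaults = list(FiO2 = 0.2093, FiCO2 = 0, P_B = 760))
  for (e in env_tl) environment_air(e$FiO2, e$FiCO2, e$P_B)  # bounds check
  work_tl <- normalize_timeline(workload, defaults = list(work = 0))
  if (any(vapply(work_tl, function(w) w$work < 0, logical(1))))
    stop_invalid("workload must be non-negative")
  bad_par <- function(given, maker) {
    unknown <- setdiff(names(given), names(formals(maker)))
    if (length(unknown))
      stop("config error: unknown parameter key(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_par(control, control_params); bad_par(metabolism, metabolic_params)
  bad_par(fatigue, fatigue_params); bad_par(blood, blood_chemistry)
  bad_par(solver, solver_settings)
  structure(list(schema_version = 1L, name = name, species = species,
                 body_mass = body_mass, duration_s = duration_s,
                 isocapnic = isTRUE(isocapnic),
                 environment = env_tl, workload = work_tl,
                 treadmill = treadmill, damage = damage,
                 control = control, metabolism = metabolism,
                 fatigue = fatigue, blood = blood, solver = solver,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

normalize_timeline <- function(tl, defaults) {
  if (is.null(tl) || length(tl) == 0) tl <- list(list(t = 0))
  tl <- lapply(tl, as.list)
  ts <- vapply(tl, function(e) as.numeric(e$t %||% 0), numeric(1))
  if (is.unsorted(ts)) stop_invalid("timeline entries must be ordered in time")
  cur <- defaults
  out <- vector("list", length(tl))
  for (i in seq_along(tl)) {
    cur <- utils::modifyList(cur, tl[[i]][setdiff(names(tl[[i]]), "t")])
    out[[i]] <- c(list(t = ts[i]), cur)
  }
  out
}

timeline_at <- function(tl, t) {
  ts <- vapply(tl, `[[`, numeric(1), "t")
  tl[[max(which(ts <= t + 1e-9))]]
}

environment_at <- function(config, t) {
  e <- timeline_at(config$environment, t)
  environment_air(e$FiO2, e$FiCO2, e$P_B)
}

workload_at <- function(config, t, mp) {
  if (!is.null(config$treadmill)) {
    tm <- config$treadmill
    speed <- if (identical(tm$protocol, "sheep_ramp")) sheep_ramp_speed(t)
             else tm$speed %||% 0
    return(treadmill_work(speed, tm$grade %||% 0, config$body_mass,
                          tm$c_level %||% 1.5))
  }
  timeline_at(config$workload, t)$work
}

config_damage <- function(model, config) {
  d <- config$damage
  if (is.null(d)) return(healthy_damage(model))
  if (!is.null(d$shunt) || !is.null(d$dl_reduction))
    return(uniform_damage(model, d$shunt %||% 0, d$dl_reduction %||% 0))
  k_w <- d$k_w %||% 0.25
  if (!is.null(d$uniform))
    return(damage_from_weight_change(model, d$uniform, k_w))
  if (!is.null(d$region))
    return(damage_from_weight_change(model,
                                     list(region = d$region, dW = d$dW), k_w))
  if (!is.null(d$per_segment)) {
    dW <- unlist(d$per_segment)
    return(damage_from_weight_change(model, dW, k_w))
  }
  stop("config error: unrecognized damage specification", call. = FALSE)
}

#' Load a scenario configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) scenario file, validates it against
#' the schema and fills defaults. Unknown top-level keys are rejected with a
#' message listing them.
#'
#' @param path Path to the file.
#' @return A `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PDM_CONFIG_KEYS)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scenario_config, raw)
}

#' Serialize a scenario configuration to YAML
#'
#' @param config A `scenario_config`.
#' @param path Output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' List shipped scenario presets
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() {
  dir <- system.file("presets", package = "pulmodpm")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Load a shipped preset scenario
#'
#' @param name Preset name (see [list_presets()]).
#' @return A `scenario_config`.
#' @export
load_preset <- function(name) {
  path <- system.file("presets", paste0(name, ".yaml"), package = "pulmodpm")
  if (!nzchar(path))
    stop("config error: unknown preset '", name, "'; available: ",
         paste(list_presets(), collapse = ", "), call. = FALSE)
  load_config(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario config '%s': %s %.0f kg, %.0f s%s\n",
              x$name %||% "unnamed", x$species, x$body_mass, x$duration_s,
              if (x$isocapnic) ", isocapnic" else ""))
  invisible(x)
}

#' Build a miniature analytic-friendly fixture lung
#'
#' A toy lung with a single tracheal airway compartment feeding `n_segments`
#' equal-volume segments, for analytic oracles and symmetry tests. The
#' airway and dead-space volumes are kept small so alveolar ventilation is
#' essentially the full tidal volume.
#'
#' @param n_segments Number of segments (>= 1).
#' @param heights Segment heights (% from base); default all 50, or
#'   `c(0, 100)` style vectors for asymmetry studies.
#' @param frc_ml Total alveolar volume, ml.
#' @param airway_ml Tracheal compartment volume, ml.
#' @param V_capillary Capillary volume, ml.
#' @return A `lung_model` of species `"human"` flagged as a fixture.
#' @export
make_fixture_lung <- function(n_segments = 1, heights = rep(50, n_segments),
                              frc_ml = 3000, airway_ml = 5,
                              V_capillary = 75) {
  if (n_segments < 1) stop_invalid("n_segments must be >= 1")
  stopifnot(length(heights) == n_segments)
  aw <- data.frame(id = 1L, volume_ml = airway_ml)
  seg <- data.frame(id = seq_len(n_segments) + 18L,
                    volume_pct = rep(100 / n_segments, n_segments),
                    height_pct = heights,
                    side = rep(c("right", "left"), length.out = n_segments))
  tree <- data.frame(parent_id = integer(0), child_id = integer(0))
  smap <- data.frame(leaf_id = rep(1L, n_segments), segment_id = seg$id)
  m <- new_lung_model("human", 70, 70, aw, seg, tree, smap,
                      frc_ml = frc_ml, deadspace_total_ml = airway_ml + 1,
                      D_L_O2_ref = PDM_DEFAULTS$D_L_O2_ref,
                      D_L_CO2 = PDM_DEFAULTS$D_L_CO2,
                      V_capillary = V_capillary,
                      shunt_baseline = 0)
  m$fixture <- TRUE
  m
}

#' Generate synthetic damage-calibration points
#'
#' Reproducible stand-in for figure-read calibration data: points scattered
#' about a known shunt-vs-damage line with Gaussian noise, suitable for
#' exercising [fit_damage_line()].
#'
#' @param slope True slope (shunt per unit x).
#' @param intercept True intercept.
#' @param noise_sd Gaussian noise standard deviation on shunt (>= 0).
#' @param n Number of points (>= 2).
#' @param seed Integer seed; identical seeds give identical data.
#' @param x_range Range of the damage axis.
#' @param x_kind Label for the x variable (`"dl_reduction"` or
#'   `"weight_gain"`).
#' @param path Optional CSV output path (columns condition, x_kind, x_value,
#'   shunt).
#' @return Data frame of calibration points (synthetic).
#' @export
generate_calibration_data <- function(slope = 0.15, intercept = 0,
                                      noise_sd = 0.01, n = 20, seed = 1,
                                      x_range = c(0, 1),
                                      x_kind = "dl_reduction", path = NULL) {
  if (n < 2 || noise_sd < 0) stop_invalid("need n >= 2 and noise_sd >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  x <- seq(x_range[1], x_range[2], length.out = n)
  shunt <- intercept + slope * x + stats::rnorm(n, 0, noise_sd)
  out <- data.frame(condition = sprintf("synthetic_%02d", seq_len(n)),
                    x_kind = x_kind, x_value = x, shunt = shunt)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
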