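## Configuration loading and the built-in device preset.
##
## Configs are YAML with units spelled out in the key names (radius_cm,
## total_current_A, ...). load_config() validates every field and normalizes
## to SI; build_preset() turns a config into ready-to-use model objects.

cfg_get <- function(cfg, path, default = NULL, required = is.null(default)) {
  node <- cfg
  for (key in strsplit(path, "/", fixed = TRUE)[[1]]) {
    if (!is.list(node) || is.null(node[[key]])) {
      if (required) stop_config("config field missing: ", path)
      return(default)
    }
    node <- node[[key]]
  }
  node
}

cfg_num <- function(cfg, path, min = -Inf, max = Inf, default = NULL, len = 1L) {
  v <- cfg_get(cfg, path, default)
  if (!is.numeric(v) || (!is.na(len) && length(v) != len) || any(!is.finite(v)))
    stop_config("config field ", path, " must be finite numeric")
  if (any(v < min) || any(v > max))
    stop_config("config field ", path, " = ", paste(v, collapse = ", "),
                " outside [", min, ", ", max, "]")
  v
}

#' Load and validate a device configuration
#'
#' Reads a YAML configuration (geometry in cm, currents in A, see the shipped
#' `biomag1.yaml` for the schema), checks every field against the model
#' invariants with field-level error messages, and returns the values
#' normalized to SI units.
#'
#' @param path YAML file path.
#' @return a validated config of class `bm_config` (nested list, SI units).
#' @seealso [build_preset()], [biomag1_preset()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- list(name = cfg_get(raw, "name", default = "unnamed"))

  n_coils <- cfg_num(raw, "array/n_coils", min = 1)
  total_i <- cfg_num(raw, "array/total_current_A", min = -1e4, max = 1e4)
  cfg$array <- list(
    n_coils = as.integer(n_coils),
    arrangement = cfg_get(raw, "array/arrangement", default = "triangular"),
    total_current = total_i,
    current_per_coil = cfg_num(raw, "array/current_per_coil_A",
                               default = total_i / n_coils, min = -1e4, max = 1e4),
    coil = list(
      inner_radius = cfg_num(raw, "array/coil/inner_radius_cm", min = 1e-4) / 100,
      height = cfg_num(raw, "array/coil/height_cm", min = 1e-4) / 100,
      turns = as.integer(cfg_num(raw, "array/coil/turns", min = 1)),
      wire_awg = as.integer(cfg_num(raw, "array/coil/wire_awg", min = 1)),
      wire_pitch = cfg_num(raw, "array/coil/wire_pitch_mm", min = 1e-4) / 1000
    ),
    core = list(
      radius = cfg_num(raw, "array/core/radius_cm", min = 1e-4) / 100,
      height = cfg_num(raw, "array/core/height_cm", min = 1e-4) / 100,
      mu_r = cfg_num(raw, "array/core/mu_r", min = 1),
      b_sat = cfg_num(raw, "array/core/b_sat_T", min = 1e-6)
    )
  )
  if (cfg$array$core$radius > cfg$array$coil$inner_radius + 1e-12)
    stop_config("config invariant violated: array/core/radius_cm exceeds array/coil/inner_radius_cm")

  cfg$container <- list(
    volume = cfg_num(raw, "container/volume_L", min = 0.01) / 1000,
    diameter = cfg_num(raw, "container/diameter_cm", min = 0.1) / 100,
    height = cfg_num(raw, "container/height_cm", min = 0.1) / 100,
    liquid_height = cfg_num(raw, "container/liquid_height_cm", min = 0.1) / 100
  )

  cfg$sizing <- list(
    heater = list(
      mass = cfg_num(raw, "sizing/heater/mass_g", min = 1),
      t_initial = cfg_num(raw, "sizing/heater/t_initial_C"),
      t_final = cfg_num(raw, "sizing/heater/t_final_C"),
      heating_time = cfg_num(raw, "sizing/heater/heating_time_min", min = 1e-3) * 60,
      cp = cfg_num(raw, "sizing/heater/cp_J_per_gK", min = 1e-3, default = 4.1806)
    ),
    mixing = list(
      fluid_density = cfg_num(raw, "sizing/mixing/fluid_density_kg_m3", min = 1),
      dynamic_viscosity = cfg_num(raw, "sizing/mixing/dynamic_viscosity_Pa_s", min = 1e-8),
      impeller_diameter = cfg_num(raw, "sizing/mixing/impeller_diameter_cm", min = 0.1) / 100,
      speed_rpm = cfg_num(raw, "sizing/mixing/speed_rpm", min = 0),
      power_number = cfg_num(raw, "sizing/mixing/power_number", min = 0.01)
    ),
    wire = list(
      mass = cfg_num(raw, "sizing/wire/mass_lb", min = 1e-4) * KG_PER_LB,
      current = cfg_num(raw, "sizing/wire/current_A", min = 0),
      v_max = cfg_num(raw, "sizing/wire/v_max_V", min = 0),
      candidates_awg = as.integer(cfg_num(raw, "sizing/wire/candidates_awg",
                                          min = 1, len = NA))
    )
  )
  if (cfg$sizing$heater$t_final < cfg$sizing$heater$t_initial)
    stop_config("config invariant violated: sizing/heater/t_final_C below t_initial_C")

  temp <- list(
    gain = cfg_num(raw, "control/temperature/gain_C_per_V"),
    time_constant = cfg_num(raw, "control/temperature/time_constant_s", min = 1e-6),
    dead_time = cfg_num(raw, "control/temperature/dead_time_s", min = 0),
    ambient = cfg_num(raw, "control/temperature/ambient_C"),
    pid = lapply(c(kp = "kp", ki = "ki", kd = "kd"), function(k)
      cfg_num(raw, paste0("control/temperature/pid/", k))),
    v_line = cfg_num(raw, "control/temperature/v_line_V", min = 1),
    duty_period = cfg_num(raw, "control/temperature/duty_period_s", min = 1e-3),
    setpoints = cfg_num(raw, "control/temperature/setpoints_C", len = NA)
  )
  ph <- list(
    volume = cfg_num(raw, "control/ph/volume_L", min = 1e-3),
    acid_conc = cfg_num(raw, "control/ph/acid_M", min = 1e-6),
    base_conc = cfg_num(raw, "control/ph/base_M", min = 1e-6),
    drop_volume = cfg_num(raw, "control/ph/drop_uL", min = 1e-3) * 1e-6,
    pulse_s = cfg_num(raw, "control/ph/pulse_s", min = 1e-3),
    drop_rate = cfg_num(raw, "control/ph/drop_rate_per_s", min = 1e-3),
    settle_s = cfg_num(raw, "control/ph/settle_s", min = 0),
    noise_sd = cfg_num(raw, "control/ph/noise_sd", min = 0),
    filter_window = as.integer(cfg_num(raw, "control/ph/filter_window", min = 1)),
    scenarios = lapply(cfg_get(raw, "control/ph/scenarios"), function(s) {
      b <- s$band
      if (!is.numeric(b) || length(b) != 2 || b[1] >= b[2])
        stop_config("config field control/ph/scenarios band must be c(low, high), low < high")
      list(initial_ph = s$initial_ph, band = as.numeric(b))
    })
  )
  stirrer <- list(
    gain = cfg_num(raw, "control/stirrer/gain_rpm", min = 1),
    time_constant = cfg_num(raw, "control/stirrer/time_constant_s", min = 1e-6),
    noise_sd = cfg_num(raw, "control/stirrer/noise_sd_rpm", min = 0),
    filter_window = as.integer(cfg_num(raw, "control/stirrer/filter_window", min = 1)),
    pid = lapply(c(kp = "kp", ki = "ki", kd = "kd"), function(k)
      cfg_num(raw, paste0("control/stirrer/pid/", k))),
    setpoints = cfg_num(raw, "control/stirrer/setpoints_rpm", len = NA, min = 0)
  )
  cfg$control <- list(temperature = temp, ph = ph, stirrer = stirrer)
  class(cfg) <- "bm_config"
  cfg
}

#' Serialize a validated config back to YAML
#'
#' Writes the SI-normalized config in the same unit-suffixed schema that
#' [load_config()] reads, so `load_config(write_config(cfg, f))` reproduces
#' `cfg` exactly.
#'
#' @param cfg a `bm_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "bm_config"))
  out <- list(
    name = cfg$name,
    array = list(
      n_coils = cfg$array$n_coils,
      arrangement = cfg$array$arrangement,
      total_current_A = cfg$array$total_current,
      current_per_coil_A = cfg$array$current_per_coil,
      coil = list(inner_radius_cm = cfg$array$coil$inner_radius * 100,
                  height_cm = cfg$array$coil$height * 100,
                  turns = cfg$array$coil$turns,
                  wire_awg = cfg$array$coil$wire_awg,
                  wire_pitch_mm = cfg$array$coil$wire_pitch * 1000),
      core = list(radius_cm = cfg$array$core$radius * 100,
                  height_cm = cfg$array$core$height * 100,
                  mu_r = cfg$array$core$mu_r,
                  b_sat_T = cfg$array$core$b_sat)
    ),
    container = list(volume_L = cfg$container$volume * 1000,
                     diameter_cm = cfg$container$diameter * 100,
                     height_cm = cfg$container$height * 100,
                     liquid_height_cm = cfg$container$liquid_height * 100),
    sizing = list(
      heater = list(mass_g = cfg$sizing$heater$mass,
                    t_initial_C = cfg$sizing$heater$t_initial,
                    t_final_C = cfg$sizing$heater$t_final,
                    heating_time_min = cfg$sizing$heater$heating_time / 60,
                    cp_J_per_gK = cfg$sizing$heater$cp),
      mixing = list(fluid_density_kg_m3 = cfg$sizing$mixing$fluid_density,
                    dynamic_viscosity_Pa_s = cfg$sizing$mixing$dynamic_viscosity,
                    impeller_diameter_cm = cfg$sizing$mixing$impeller_diameter * 100,
                    speed_rpm = cfg$sizing$mixing$speed_rpm,
                    power_number = cfg$sizing$mixing$power_number),
      wire = list(mass_lb = cfg$sizing$wire$mass / KG_PER_LB,
                  current_A = cfg$sizing$wire$current,
                  v_max_V = cfg$sizing$wire$v_max,
                  candidates_awg = cfg$sizing$wire$candidates_awg)
    ),
    control = list(
      temperature = list(gain_C_per_V = cfg$control$temperature$gain,
                         time_constant_s = cfg$control$temperature$time_constant,
                         dead_time_s = cfg$control$temperature$dead_time,
                         ambient_C = cfg$control$temperature$ambient,
                         pid = cfg$control$temperature$pid,
                         v_line_V = cfg$control$temperature$v_line,
                         duty_period_s = cfg$control$temperature$duty_period,
                         setpoints_C = cfg$control$temperature$setpoints),
      ph = list(volume_L = cfg$control$ph$volume,
                acid_M = cfg$control$ph$acid_conc,
                base_M = cfg$control$ph$base_conc,
                drop_uL = cfg$control$ph$drop_volume * 1e6,
                pulse_s = cfg$control$ph$pulse_s,
                drop_rate_per_s = cfg$control$ph$drop_rate,
                settle_s = cfg$control$ph$settle_s,
                noise_sd = cfg$control$ph$noise_sd,
                filter_window = cfg$control$ph$filter_window,
                scenarios = cfg$control$ph$scenarios),
      stirrer = list(gain_rpm = cfg$control$stirrer$gain,
                     time_constant_s = cfg$control$stirrer$time_constant,
                     noise_sd_rpm = cfg$control$stirrer$noise_sd,
                     filter_window = cfg$control$stirrer$filter_window,
                     pid = cfg$control$stirrer$pid,
                     setpoints_rpm = cfg$control$stirrer$setpoints)
    )
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Build model objects from a validated config
#'
#' @param cfg a `bm_config` from [load_config()].
#' @return a list of class `bm_preset` with components `config`,
#'   `electromagnet` (the template unit), `array` (the placed [em_array()]),
#'   `heater` ([heater_spec()]), `mixing` ([mixing_spec()]), `wire_gauge`,
#'   `temperature_plant` ([fopdt_plant()]), `temperature_pid`,
#'   `ph_scenarios` (list of [ph_plant()]) and `stirrer_plants`
#'   (list of [stirrer_plant()], one per configured setpoint).
#' @export
build_preset <- function(cfg) {
  stopifnot(inherits(cfg, "bm_config"))
  coil <- cfg$array$coil
  winding <- winding_spec(coil$inner_radius, coil$height, coil$turns,
                          coil$wire_pitch, cfg$array$current_per_coil)
  core <- core_spec(cfg$array$core$radius, cfg$array$core$height,
                    cfg$array$core$mu_r, cfg$array$core$b_sat)
  em <- electromagnet(winding, core)
  arr <- if (cfg$array$n_coils == 3 && identical(cfg$array$arrangement, "triangular")) {
    triangular_array(em)
  } else if (cfg$array$n_coils == 1) {
    em_array(em)
  } else {
    ## general ring placement for other counts
    r <- 2 / sqrt(3) * winding$inner_radius
    ang <- 2 * pi * (seq_len(cfg$array$n_coils) - 1) / cfg$array$n_coils + pi / 2
    em_array(lapply(ang, function(a)
      electromagnet(winding, core, point3(r * cos(a), r * sin(a), 0))))
  }
  hs <- cfg$sizing$heater
  ms <- cfg$sizing$mixing
  tc <- cfg$control$temperature
  ph <- cfg$control$ph
  stc <- cfg$control$stirrer
  structure(list(
    config = cfg,
    electromagnet = em,
    array = arr,
    heater = heater_spec(hs$mass, hs$t_initial, hs$t_final, hs$heating_time, hs$cp),
    mixing = mixing_spec(ms$fluid_density, ms$dynamic_viscosity,
                         ms$impeller_diameter, ms$speed_rpm, ms$power_number),
    wire_gauge = awg_gauge(coil$wire_awg),
    temperature_plant = fopdt_plant(tc$gain, tc$time_constant, tc$dead_time, tc$ambient),
    temperature_pid = pid_gains(tc$pid$kp, tc$pid$ki, tc$pid$kd),
    temperature_setpoints = tc$setpoints,
    v_line = tc$v_line,
    duty_period = tc$duty_period,
    ph_scenarios = lapply(ph$scenarios, function(s)
      ph_plant(ph$volume, s$initial_ph, s$band, ph$acid_conc, ph$base_conc,
               ph$drop_volume, ph$pulse_s, ph$drop_rate, ph$settle_s,
               ph$noise_sd, ph$filter_window)),
    stirrer_plants = lapply(stc$setpoints, function(sp)
      stirrer_plant(sp, pid_gains(stc$pid$kp, stc$pid$ki, stc$pid$kd),
                    stc$gain, stc$time_constant, stc$noise_sd, stc$filter_window))
  ), class = "bm_preset")
}

#' The built-in reference device preset
#'
#' Loads and builds the `biomag1` preset shipped with the package: a 3 L,
#' 16 cm vessel over three mutually tangent 5 cm electromagnets (300 turns of
#' 20 AWG each, 10 A total split in parallel, A36 cores with `mu_r` 200 and a
#' 2.16 T saturation point), with the identified temperature plant, the
#' titration settings and the stirrer loop configuration.
#'
#' @param name preset name (currently only `"biomag1"`).
#' @return a `bm_preset`, see [build_preset()].
#' @examples
#' pr <- biomag1_preset()
#' pr$array
#' @export
biomag1_preset <- function(name = "biomag1") {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "magbior")
  if (path == "") stop_config("no built-in preset named '", name, "'")
  build_preset(load_config(path))
}

#' @export
print.bm_preset <- function(x, ...) {
  cat(sprintf("<bm_preset> '%s'\n", x$config$name))
  print(x$array)
  cat(sprintf("  heater %.4g W nominal; wire %d AWG; temp plant K=%g tau=%g theta=%g\n",
              heater_power(x$heater), x$wire_gauge$awg,
              x$temperature_plant$gain, x$temperature_plant$time_constant,
              x$temperature_plant$dead_time))
  invisible(x)
}
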