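## Device sizing: winding wire gauge, heater power, impeller hydrodynamics.

## Published bare copper diameters (mm), ASTM B258, gauges 14-30.
AWG_DIAMETER_MM <- c(
  `14` = 1.628, `15` = 1.450, `16` = 1.291, `17` = 1.150, `18` = 1.024,
  `19` = 0.9116, `20` = 0.8128, `21` = 0.7229, `22` = 0.6438, `23` = 0.5733,
  `24` = 0.5106, `25` = 0.4547, `26` = 0.4049, `27` = 0.3606, `28` = 0.3211,
  `29` = 0.2859, `30` = 0.2546)

#' Copper wire gauge properties
#'
#' Resistance per metre and linear mass are derived from the bare diameter
#' using copper resistivity 1.724e-8 ohm m (20 C) and density 8960 kg/m^3.
#'
#' @param awg gauge number, 14 to 30.
#' @return object of class `wire_gauge` with fields `awg`, `bare_diameter`
#'   (m), `resistance_per_m` (ohm/m) and `linear_mass` (kg/m).
#' @examples
#' awg_gauge(20)
#' @export
awg_gauge <- function(awg) {
  key <- as.character(as.integer(awg))
  if (!key %in% names(AWG_DIAMETER_MM))
    stop_config("unknown wire gauge ", awg, " AWG (table covers 14-30)")
  d <- AWG_DIAMETER_MM[[key]] * 1e-3
  area <- pi * d^2 / 4
  structure(list(awg = as.integer(awg), bare_diameter = d,
                 resistance_per_m = COPPER_RESISTIVITY / area,
                 linear_mass = COPPER_DENSITY * area),
            class = "wire_gauge")
}

#' Built-in AWG table
#'
#' @return data frame of the gauges 14-30 with diameter, resistance per metre
#'   and linear mass.
#' @export
awg_table <- function() {
  g <- lapply(as.integer(names(AWG_DIAMETER_MM)), awg_gauge)
  data.frame(awg = vapply(g, `[[`, 0L, "awg"),
             bare_diameter_m = vapply(g, `[[`, 0, "bare_diameter"),
             resistance_per_m = vapply(g, `[[`, 0, "resistance_per_m"),
             linear_mass_kg_m = vapply(g, `[[`, 0, "linear_mass"))
}

#' @export
print.wire_gauge <- function(x, ...) {
  cat(sprintf("<wire_gauge> %d AWG: d = %.4g mm, %.4g ohm/m, %.4g g/m\n",
              x$awg, x$bare_diameter * 1e3, x$resistance_per_m, x$linear_mass * 1e3))
  invisible(x)
}

#' Electrical requirements of a winding wire budget
#'
#' Given a wire mass, the affordable length, its resistance, and the voltage
#' and power needed to drive a target current.
#'
#' @param gauge a [wire_gauge()].
#' @param wire_mass wire mass (kg).
#' @param current drive current (A).
#' @return list `length` (m), `resistance` (ohm), `voltage` (V), `power` (W).
#' @examples
#' wire_requirements(awg_gauge(20), 0.45359237 / 3, 10)$voltage  # ~10.8 V
#' @export
wire_requirements <- function(gauge, wire_mass, current) {
  stopifnot(inherits(gauge, "wire_gauge"))
  check_num(wire_mass, "wire_mass", min = 0, strict_min = TRUE)
  check_num(current, "current", min = 0)
  len <- wire_mass / gauge$linear_mass
  res <- len * gauge$resistance_per_m
  list(length = len, resistance = res,
       voltage = current * res, power = current^2 * res)
}

#' Select the thinnest feasible winding gauge
#'
#' Among candidate gauges whose [wire_requirements()] voltage at the target
#' current stays within `v_max`, returns the one with the smallest bare
#' diameter -- the thinnest wire packs the most turns per unit mass. Ties on
#' diameter break toward the larger AWG number.
#'
#' @param candidates list of [wire_gauge()] objects (or integer AWG numbers).
#' @param wire_mass wire mass budget (kg).
#' @param current drive current (A).
#' @param v_max supply voltage limit (V).
#' @return the winning `wire_gauge`.
#' @examples
#' select_gauge(c(16, 18, 20, 22), 0.45359237 / 3, 10, 15)$awg  # 20
#' @export
select_gauge <- function(candidates, wire_mass, current, v_max) {
  if (is.numeric(candidates)) candidates <- lapply(candidates, awg_gauge)
  if (length(candidates) == 0) stop_config("no candidate gauges supplied")
  volts <- vapply(candidates, function(g) wire_requirements(g, wire_mass, current)$voltage, 0)
  ok <- volts <= v_max
  if (!any(ok)) {
    i <- which.min(volts)
    stop_config(sprintf(
      "no candidate gauge meets v_max = %g V at %g A; closest is %d AWG needing %.3g V",
      v_max, current, candidates[[i]]$awg, volts[i]))
  }
  feas <- candidates[ok]
  d <- vapply(feas, `[[`, 0, "bare_diameter")
  a <- vapply(feas, `[[`, 0L, "awg")
  feas[[order(d, -a)[1]]]
}

#' Heater sizing specification
#'
#' @param mass liquid mass (g).
#' @param cp specific heat (J/(g K)); default water, 4.1806.
#' @param t_initial,t_final temperatures (C), `t_final >= t_initial`.
#' @param heating_time allowed heating time (s, > 0).
#' @return object of class `heater_spec`.
#' @export
heater_spec <- function(mass, t_initial, t_final, heating_time, cp = 4.1806) {
  check_num(mass, "mass", min = 0, strict_min = TRUE)
  check_num(cp, "cp", min = 0, strict_min = TRUE)
  check_num(t_initial, "t_initial")
  check_num(t_final, "t_final", min = t_initial)
  check_num(heating_time, "heating_time", min = 0, strict_min = TRUE)
  structure(list(mass = mass, cp = cp, t_initial = t_initial,
                 t_final = t_final, heating_time = heating_time),
            class = "heater_spec")
}

#' Heater power from a sensible-heat balance
#'
#' \deqn{P = m c_p (T_f - T_i) / \Delta t}
#' assuming conduction-only transfer into the liquid; sizes the armoured
#' band resistor around the vessel.
#'
#' @param spec a [heater_spec()].
#' @return power in watts.
#' @examples
#' heater_power(heater_spec(2500, 25, 50, 300))  # 870.96 W
#' @export
heater_power <- function(spec) {
  stopifnot(inherits(spec, "heater_spec"))
  spec$mass * spec$cp * (spec$t_final - spec$t_initial) / spec$heating_time
}

#' Stirred-tank mixing specification
#'
#' @param fluid_density fluid density (kg/m^3).
#' @param dynamic_viscosity dynamic viscosity (Pa s).
#' @param impeller_diameter impeller diameter (m).
#' @param speed impeller speed; revolutions per second unless `rpm = TRUE`.
#' @param power_number dimensionless impeller power number (5 for a standard
#'   six-blade Rushton turbine in the turbulent regime).
#' @param rpm if TRUE (default), `speed` is given in RPM and converted.
#' @return object of class `mixing_spec` (speed stored in rev/s).
#' @export
mixing_spec <- function(fluid_density, dynamic_viscosity, impeller_diameter,
                        speed, power_number = 5, rpm = TRUE) {
  check_num(fluid_density, "fluid_density", min = 0, strict_min = TRUE)
  check_num(dynamic_viscosity, "dynamic_viscosity", min = 0, strict_min = TRUE)
  check_num(impeller_diameter, "impeller_diameter", min = 0, strict_min = TRUE)
  check_num(speed, "speed", min = 0)
  check_num(power_number, "power_number", min = 0, strict_min = TRUE)
  structure(list(fluid_density = fluid_density, dynamic_viscosity = dynamic_viscosity,
                 impeller_diameter = impeller_diameter,
                 speed = if (rpm) speed / 60 else speed,
                 power_number = power_number),
            class = "mixing_spec")
}

#' Impeller Reynolds number
#'
#' \deqn{Re = \rho N_i D_i^2 / \mu} with the speed in revolutions per second.
#' The regime label uses the standard stirred-tank convention: turbulent above
#' 1e4, laminar below 10, transitional between.
#'
#' @param spec a [mixing_spec()].
#' @return list with `Re` and `regime` (`"turbulent"`, `"transitional"`, `"laminar"`).
#' @examples
#' reynolds(mixing_spec(1000, 0.001, 0.1, 100))  # ~16670, turbulent
#' @export
reynolds <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  re <- spec$fluid_density * spec$speed * spec$impeller_diameter^2 / spec$dynamic_viscosity
  regime <- if (re > 1e4) "turbulent" else if (re < 10) "laminar" else "transitional"
  list(Re = re, regime = regime)
}

#' Impeller power draw
#'
#' \deqn{P = N_p \rho N_i^3 D_i^5}, valid in the turbulent regime where the
#' power number is constant; a warning (not an error) is issued otherwise.
#'
#' @param spec a [mixing_spec()].
#' @return power in watts.
#' @examples
#' impeller_power(mixing_spec(1000, 0.001, 0.1, 100))  # ~0.23 W
#' @export
impeller_power <- function(spec) {
  stopifnot(inherits(spec, "mixing_spec"))
  if (reynolds(spec)$regime != "turbulent")
    warning("constant power number assumes the turbulent regime (Re > 1e4)")
  spec$power_number * spec$fluid_density * spec$speed^3 * spec$impeller_diameter^5
}
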