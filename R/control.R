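## Discrete-time closed-loop simulators: FOPDT temperature plant with a
## three-mode heater controller, drip-titration pH regulation, and a
## first-order stirrer speed loop. All simulators are deterministic given
## (configuration, seed).

#' PID controller gains
#'
#' @param kp,ki,kd proportional, integral and derivative constants in
#'   loop-specific units.
#' @return object of class `pid_gains`.
#' @export
pid_gains <- function(kp, ki, kd) {
  check_num(kp, "kp"); check_num(ki, "ki"); check_num(kd, "kd")
  structure(list(kp = kp, ki = ki, kd = kd), class = "pid_gains")
}

#' Fresh PID controller state
#'
#' @return list holding the integral accumulator and the previous samples used
#'   by the trapezoidal integral and the backward-difference derivative.
#' @export
pid_state <- function() {
  list(integral = 0, prev_error = NA_real_, prev_deriv_signal = NA_real_)
}

#' One step of a positional PID controller
#'
#' Positional form `u = kp e + ki int(e dt) + kd d/dt`, with a trapezoidal
#' integral and a backward-difference derivative. The derivative acts on the
#' error by default; passing `measurement` switches to
#' derivative-on-measurement (`-d(measurement)/dt`), which avoids the
#' derivative kick on setpoint changes. Anti-windup is by conditional
#' integration: the integral does not accumulate while the output is pinned at
#' a limit and the error would push it further out.
#'
#' @param gains a [pid_gains()].
#' @param error setpoint minus measurement, in plant units.
#' @param state controller state from [pid_state()] or a previous call.
#' @param dt step size (s, > 0).
#' @param umin,umax actuator limits for clamping and anti-windup.
#' @param measurement optional current measurement for
#'   derivative-on-measurement.
#' @return list with `output` (clamped) and the updated `state`.
#' @examples
#' s <- pid_state()
#' pid_step(pid_gains(2, 0, 0), 1.5, s, 1)$output  # 3
#' @export
pid_step <- function(gains, error, state, dt, umin = -Inf, umax = Inf,
                     measurement = NULL) {
  stopifnot(inherits(gains, "pid_gains"))
  check_num(dt, "dt", min = 0, strict_min = TRUE)
  dsig <- if (is.null(measurement)) error else -measurement
  deriv <- if (is.na(state$prev_deriv_signal)) 0 else (dsig - state$prev_deriv_signal) / dt
  prev_e <- if (is.na(state$prev_error)) error else state$prev_error
  cand <- state$integral + dt * (error + prev_e) / 2
  u <- gains$kp * error + gains$ki * cand + gains$kd * deriv
  if ((u > umax && error > 0) || (u < umin && error < 0)) {
    cand <- state$integral  # hold the integral while saturated outward
    u <- gains$kp * error + gains$ki * cand + gains$kd * deriv
  }
  list(output = min(max(u, umin), umax),
       state = list(integral = cand, prev_error = error, prev_deriv_signal = dsig))
}

#' First-order-plus-dead-time plant
#'
#' Transfer function \eqn{G(s) = K e^{-\theta s} / (\tau s + 1)} describing the
#' vessel temperature response to the heater's average applied voltage. The
#' reference identification for the 3 L vessel gives `gain` 1.475 C per volt,
#' `time_constant` 990 s and `dead_time` 120 s.
#'
#' @param gain steady-state gain K (C per V of average applied voltage).
#' @param time_constant time constant tau (s, > 0).
#' @param dead_time transport delay theta (s, >= 0).
#' @param ambient ambient (initial) temperature (C).
#' @return object of class `fopdt_plant`.
#' @export
fopdt_plant <- function(gain = 1.475, time_constant = 990, dead_time = 120,
                        ambient = 25) {
  check_num(gain, "gain")
  check_num(time_constant, "time_constant", min = 0, strict_min = TRUE)
  check_num(dead_time, "dead_time", min = 0)
  check_num(ambient, "ambient")
  structure(list(gain = gain, time_constant = time_constant,
                 dead_time = dead_time, ambient = ambient),
            class = "fopdt_plant")
}

#' Open-loop FOPDT response to a piecewise-constant input
#'
#' Integrates \eqn{\tau \,d\Delta T/dt = -\Delta T + K u(t - \theta)} with an
#' exact zero-order-hold exponential update per step, so a step input matches
#' the closed form \eqn{\Delta T = K u_0 (1 - e^{-(t-\theta)/\tau})} to
#' rounding error when the dead time is a multiple of `dt`.
#'
#' @param plant a [fopdt_plant()].
#' @param u input voltage: a scalar (step applied from t = 0), a function of
#'   time, or a numeric vector sampled on the output time grid.
#' @param t_end simulation horizon (s).
#' @param dt step (s); must satisfy `dt <= time_constant / 10`.
#' @return a [bm_sim] time series with `value` = temperature (C) and
#'   `actuator` = applied voltage.
#' @examples
#' ts <- fopdt_response(fopdt_plant(), 40, t_end = 5000, dt = 1)
#' tail(ts$value, 1)  # approaches 25 + 1.475 * 40
#' @export
fopdt_response <- function(plant, u, t_end, dt) {
  stopifnot(inherits(plant, "fopdt_plant"))
  check_num(t_end, "t_end", min = 0, strict_min = TRUE)
  check_num(dt, "dt", min = 0, strict_min = TRUE)
  if (dt > plant$time_constant / 10)
    stop_config("dt = ", dt, " s too coarse: must be <= time_constant/10 = ",
                plant$time_constant / 10, " s")
  t <- seq(0, t_end, by = dt)
  n <- length(t)
  uvec <- if (is.function(u)) vapply(t, u, 0)
          else if (length(u) == 1) rep(as.numeric(u), n)
          else if (length(u) == n) as.numeric(u)
          else stop_config("u must be a scalar, a function of t, or length ", n)
  dlag <- round(plant$dead_time / dt)
  decay <- exp(-dt / plant$time_constant)
  dT <- numeric(n)
  for (i in seq_len(n - 1)) {
    ud <- if (i - dlag >= 1) uvec[i - dlag] else 0
    dT[i + 1] <- decay * dT[i] + (1 - decay) * plant$gain * ud
  }
  bm_sim(t, plant$ambient + dT, uvec, rep("open-loop", n), kind = "fopdt_response",
         summary = list(final = plant$ambient + dT[n]))
}

#' Temperature loop configuration
#'
#' The heater controller has three modes: full power until the temperature has
#' risen `pid_activation_fraction` of the commanded change, then PID duty
#' modulation, and off whenever the setpoint is reached (PID re-engages when
#' the temperature falls below it again). The AC relay modulates the line
#' voltage over `duty_period`; the plant sees the duty-average voltage.
#'
#' @param setpoint target temperature (C).
#' @param pid a [pid_gains()]; reference tuning `pid_gains(3.3, 0.0033, 82.5)`.
#' @param v_line line voltage (V), default 120.
#' @param duty_period relay switching period (s), default 5; the controller
#'   output is refreshed once per period.
#' @param pid_activation_fraction fraction of the commanded temperature change
#'   after which mode 1 hands over to the PID (default 0.2).
#' @param tolerance_band settling band (C), default 1.
#' @param pid_output `"volts"` (default): the PID output is an average voltage,
#'   converted to a duty fraction; `"duty"`: the PID output is the duty
#'   fraction itself (raises the effective loop gain by `v_line`).
#' @return object of class `temp_control_config`.
#' @export
temp_control_config <- function(setpoint, pid = pid_gains(3.3, 0.0033, 82.5),
                                v_line = 120, duty_period = 5,
                                pid_activation_fraction = 0.2,
                                tolerance_band = 1,
                                pid_output = c("volts", "duty")) {
  check_num(setpoint, "setpoint")
  stopifnot(inherits(pid, "pid_gains"))
  check_num(v_line, "v_line", min = 0, strict_min = TRUE)
  check_num(duty_period, "duty_period", min = 0, strict_min = TRUE)
  check_num(pid_activation_fraction, "pid_activation_fraction", min = 0, max = 1,
            strict_min = TRUE)
  if (pid_activation_fraction >= 1) stop_config("pid_activation_fraction must be < 1")
  check_num(tolerance_band, "tolerance_band", min = 0, strict_min = TRUE)
  structure(list(setpoint = setpoint, pid = pid, v_line = v_line,
                 duty_period = duty_period,
                 pid_activation_fraction = pid_activation_fraction,
                 tolerance_band = tolerance_band,
                 pid_output = match.arg(pid_output)),
            class = "temp_control_config")
}

#' Closed-loop temperature simulation (three-mode heater controller)
#'
#' Simulates the FOPDT vessel under the three-mode logic of
#' [temp_control_config()]. The controller refreshes once per duty period;
#' within a period the duty-average voltage is held. Reports overshoot,
#' steady-state error (mean absolute error over the final tenth of the run)
#' and stabilization time (first time from which the absolute error stays
#' inside the tolerance band).
#'
#' @param plant a [fopdt_plant()].
#' @param cfg a [temp_control_config()]; `setpoint >= ambient` required.
#' @param t_end horizon (s).
#' @param dt step (s), default 1.
#' @return a [bm_sim] time series (`value` = C, `actuator` = applied average
#'   voltage, `mode` in `full-power/pid/off`) with a summary attribute.
#' @examples
#' \donttest{
#' sim <- simulate_temperature(fopdt_plant(), temp_control_config(35), 20000, 1)
#' summary(sim)
#' }
#' @export
simulate_temperature <- function(plant, cfg, t_end, dt = 1) {
  stopifnot(inherits(plant, "fopdt_plant"), inherits(cfg, "temp_control_config"))
  if (cfg$setpoint < plant$ambient)
    stop_config("setpoint below ambient: this loop only heats")
  t <- seq(0, t_end, by = dt)
  n <- length(t)
  dlag <- round(plant$dead_time / dt)
  decay <- exp(-dt / plant$time_constant)
  per <- max(1L, round(cfg$duty_period / dt))
  t0 <- plant$ambient
  dchange <- cfg$setpoint - t0
  threshold <- t0 + cfg$pid_activation_fraction * dchange
  umax <- if (cfg$pid_output == "volts") cfg$v_line else 1
  temp <- numeric(n); temp[1] <- t0
  volts <- numeric(n)
  mode <- character(n)
  st <- pid_state()
  in_pid_region <- temp[1] >= threshold
  v_now <- 0; mode_now <- "off"
  for (i in seq_len(n)) {
    Tc <- temp[i]
    if (!in_pid_region && Tc >= threshold) in_pid_region <- TRUE
    if ((i - 1L) %% per == 0L) {          # controller refresh instant
      if (!in_pid_region) {
        v_now <- cfg$v_line; mode_now <- "full-power"
      } else if (Tc >= cfg$setpoint) {
        v_now <- 0; mode_now <- "off"
        st$prev_error <- NA_real_        # PID restarts cleanly on re-entry
        st$prev_deriv_signal <- NA_real_
      } else {
        res <- pid_step(cfg$pid, cfg$setpoint - Tc, st, dt * per,
                        umin = 0, umax = umax, measurement = Tc)
        st <- res$state
        duty <- if (cfg$pid_output == "volts") res$output / cfg$v_line else res$output
        v_now <- min(max(duty, 0), 1) * cfg$v_line
        mode_now <- "pid"
      }
    }
    if (in_pid_region && Tc >= cfg$setpoint) { v_now <- 0; mode_now <- "off" }
    volts[i] <- v_now; mode[i] <- mode_now
    if (i < n) {
      ud <- if (i - dlag >= 1) volts[i - dlag] else 0
      temp[i + 1] <- plant$ambient + decay * (temp[i] - plant$ambient) +
        (1 - decay) * plant$gain * ud
    }
  }
  err <- temp - cfg$setpoint
  tail_idx <- seq(floor(0.9 * n) + 1L, n)
  ok <- abs(err) < cfg$tolerance_band
  stab <- settle_time(t, ok)
  bm_sim(t, temp, volts, mode, kind = "temperature",
         summary = list(setpoint = cfg$setpoint,
                        overshoot = max(0, max(temp) - cfg$setpoint),
                        steady_state_error = mean(abs(err[tail_idx])),
                        stabilization_time = stab,
                        final = temp[n]))
}

## first time index from which `ok` stays TRUE to the end
settle_time <- function(t, ok) {
  if (!any(ok)) return(NA_real_)
  r <- rev(cumprod(rev(ok)))   # 1 where ok holds through the end
  if (r[1] == 1) return(t[1])
  i <- which(r == 1)
  if (length(i) == 0) NA_real_ else t[min(i)]
}

#' Drip-titration pH plant and controller settings
#'
#' A well-mixed, unbuffered volume whose pH is corrected by timed pulses of
#' strong acid (HCl) or strong base (NaOH) from a drip chamber: when the
#' (filtered) reading leaves the band, the corresponding valve opens for
#' `pulse_s` seconds at `drop_rate` drops per second, then the controller
#' waits `settle_s` seconds for mixing before deciding again.
#'
#' @param volume liquid volume (L).
#' @param initial_ph starting pH (0-14 exclusive).
#' @param band acceptable range `c(low, high)`.
#' @param acid_conc,base_conc titrant concentrations (mol/L); defaults 0.47
#'   (HCl) and 0.5 (NaOH).
#' @param drop_volume volume per drop (L); default 50 uL, the standard
#'   20-drops-per-mL drip chamber.
#' @param pulse_s valve-open time per correction (s), default 3.
#' @param drop_rate drip rate while open (drops/s), default 1.
#' @param settle_s mixing wait after each pulse (s), default 5.
#' @param noise_sd sensor noise standard deviation (pH units), default 0.05.
#' @param filter_window trailing moving-average window applied to the sensed
#'   signal before control decisions, default 5 samples.
#' @return object of class `ph_plant`.
#' @export
ph_plant <- function(volume, initial_ph, band, acid_conc = 0.47, base_conc = 0.5,
                     drop_volume = 5e-5, pulse_s = 3, drop_rate = 1,
                     settle_s = 5, noise_sd = 0.05, filter_window = 5) {
  check_num(volume, "volume", min = 0, strict_min = TRUE)
  check_num(initial_ph, "initial_ph", min = 0, max = 14, strict_min = TRUE)
  check_num(band, "band", len = 2)
  if (band[1] >= band[2]) stop_config("band must satisfy low < high")
  check_num(acid_conc, "acid_conc", min = 0, strict_min = TRUE)
  check_num(base_conc, "base_conc", min = 0, strict_min = TRUE)
  check_num(drop_volume, "drop_volume", min = 0, strict_min = TRUE)
  check_num(pulse_s, "pulse_s", min = 0, strict_min = TRUE)
  check_num(drop_rate, "drop_rate", min = 0, strict_min = TRUE)
  check_num(settle_s, "settle_s", min = 0)
  check_num(noise_sd, "noise_sd", min = 0)
  check_num(filter_window, "filter_window", min = 1)
  structure(list(volume = volume, initial_ph = initial_ph, band = band,
                 acid_conc = acid_conc, base_conc = base_conc,
                 drop_volume = drop_volume, pulse_s = pulse_s,
                 drop_rate = drop_rate, settle_s = settle_s,
                 noise_sd = noise_sd, filter_window = filter_window),
            class = "ph_plant")
}

## strong acid/base charge balance: net strong-acid concentration c satisfies
## [H+] - Kw/[H+] = c  =>  [H+] = (c + sqrt(c^2 + 4 Kw)) / 2
ph_from_net_acid <- function(c) -log10((c + sqrt(c^2 + 4 * KW_WATER)) / 2)
net_acid_from_ph <- function(ph) { h <- 10^(-ph); h - KW_WATER / h }

#' Closed-loop pH simulation (band controller with drip titration)
#'
#' Event loop per [ph_plant()]: sense (with seeded Gaussian noise and a
#' trailing moving-average filter), dispense a timed pulse of acid or base
#' when the filtered reading leaves the band, wait for mixing, repeat. The
#' chemistry is an unbuffered strong acid/strong base charge balance on a
#' well-mixed volume; dispensed moles and volume are conserved exactly.
#'
#' @param plant a [ph_plant()].
#' @param t_end horizon (s).
#' @param dt step (s), default 1 (the sensor sampling period).
#' @param seed integer seed for the sensor noise (default 1).
#' @param max_events dispensing-pulse limit; exceeded means the band is
#'   unreachable with the configured reagents and raises an error.
#' @return a [bm_sim] time series (`value` = true pH, `actuator` = signed
#'   drops per step, negative for acid; `mode` in `idle/acid/base/settle`)
#'   with a summary attribute (`final_ph`, `in_band`, drop totals,
#'   `stabilization_time`).
#' @examples
#' sim <- simulate_ph(ph_plant(3, 7, c(4.5, 5.5)), t_end = 300)
#' summary(sim)
#' @export
simulate_ph <- function(plant, t_end, dt = 1, seed = 1L, max_events = 1000L) {
  stopifnot(inherits(plant, "ph_plant"))
  check_num(t_end, "t_end", min = 0, strict_min = TRUE)
  check_num(dt, "dt", min = 0, strict_min = TRUE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  t <- seq(0, t_end, by = dt)
  n <- length(t)
  vol <- plant$volume
  moles <- net_acid_from_ph(plant$initial_ph) * vol
  ph <- numeric(n); drops <- numeric(n); mode <- character(n)
  sensed_buf <- numeric(0)
  phase <- "ready"; phase_left <- 0; dispensing <- ""   # current pulse reagent
  events <- 0L; acid_total <- 0; base_total <- 0; last_event_end <- 0
  for (i in seq_len(n)) {
    ph_true <- ph_from_net_acid(moles / vol)
    ph[i] <- ph_true
    sensed <- ph_true + rnorm(1, 0, plant$noise_sd)
    sensed_buf <- c(sensed_buf, sensed)
    if (length(sensed_buf) > plant$filter_window)
      sensed_buf <- sensed_buf[-1]
    filtered <- mean(sensed_buf)
    mode[i] <- "idle"
    if (phase == "dispense") {
      d <- plant$drop_rate * dt
      dv <- d * plant$drop_volume
      if (dispensing == "acid") {
        moles <- moles + dv * plant$acid_conc
        acid_total <- acid_total + d
        drops[i] <- -d
      } else {
        moles <- moles - dv * plant$base_conc
        base_total <- base_total + d
        drops[i] <- d
      }
      vol <- vol + dv
      mode[i] <- dispensing
      phase_left <- phase_left - dt
      if (phase_left <= 1e-9) { phase <- "settle"; phase_left <- plant$settle_s }
    } else if (phase == "settle") {
      mode[i] <- "settle"
      phase_left <- phase_left - dt
      if (phase_left <= 1e-9) { phase <- "ready"; last_event_end <- t[i] + dt }
    } else {
      if (filtered > plant$band[2]) {
        phase <- "dispense"; dispensing <- "acid"; phase_left <- plant$pulse_s
        events <- events + 1L
      } else if (filtered < plant$band[1]) {
        phase <- "dispense"; dispensing <- "base"; phase_left <- plant$pulse_s
        events <- events + 1L
      }
      if (events > max_events)
        stop_domain("pH band unreachable with the configured reagents: ",
                    max_events, " correction pulses exhausted")
    }
  }
  final_ph <- ph[n]
  bm_sim(t, ph, drops, mode, kind = "ph",
         summary = list(final_ph = final_ph,
                        in_band = final_ph >= plant$band[1] && final_ph <= plant$band[2],
                        drops_acid = acid_total, drops_base = base_total,
                        events = events,
                        stabilization_time = last_event_end))
}

#' Stirrer speed plant and controller settings
#'
#' First-order DC motor model \eqn{\dot\omega = (G u - \omega)/\tau_m} with
#' drive `u` in `[0, 1]` (PWM fraction), seeded Gaussian measurement noise on
#' the encoder reading, and a trailing moving-average filter before the PID.
#' The motor defaults (`gain` 130 RPM at full drive, `time_constant` 0.3 s)
#' describe a small geared DC motor rated around 100 RPM under load; they are
#' plumbing defaults for the simulator, not identified constants.
#'
#' @param setpoint target speed (RPM); the device accepts 25-100 RPM.
#' @param pid a [pid_gains()]; reference tuning `pid_gains(0.18, 0.8, 0.0016)`.
#' @param gain full-drive speed (RPM).
#' @param time_constant motor time constant (s, > 0).
#' @param noise_sd encoder noise standard deviation (RPM), default 2.
#' @param filter_window moving-average window (samples), default 5.
#' @return object of class `stirrer_plant`.
#' @export
stirrer_plant <- function(setpoint, pid = pid_gains(0.18, 0.8, 0.0016),
                          gain = 130, time_constant = 0.3,
                          noise_sd = 2, filter_window = 5) {
  check_num(setpoint, "setpoint", min = 0)
  stopifnot(inherits(pid, "pid_gains"))
  check_num(gain, "gain", min = 0, strict_min = TRUE)
  check_num(time_constant, "time_constant", min = 0, strict_min = TRUE)
  check_num(noise_sd, "noise_sd", min = 0)
  check_num(filter_window, "filter_window", min = 1)
  structure(list(setpoint = setpoint, pid = pid, gain = gain,
                 time_constant = time_constant, noise_sd = noise_sd,
                 filter_window = filter_window),
            class = "stirrer_plant")
}

#' Closed-loop stirrer speed simulation
#'
#' @param plant a [stirrer_plant()].
#' @param t_end horizon (s).
#' @param dt step (s), default 0.01 (the encoder loop period).
#' @param seed integer seed for the measurement noise (default 1).
#' @return a [bm_sim] time series (`value` = speed in RPM, `actuator` = drive
#'   fraction) with a summary attribute including `final_speed` (mean over the
#'   last tenth) and `band_occupancy` (fraction of the last half of the run
#'   within +/- 10 RPM of the setpoint).
#' @examples
#' sim <- simulate_stirrer(stirrer_plant(50), t_end = 20)
#' summary(sim)
#' @export
simulate_stirrer <- function(plant, t_end, dt = 0.01, seed = 1L) {
  stopifnot(inherits(plant, "stirrer_plant"))
  check_num(t_end, "t_end", min = 0, strict_min = TRUE)
  check_num(dt, "dt", min = 0, strict_min = TRUE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  t <- seq(0, t_end, by = dt)
  n <- length(t)
  decay <- exp(-dt / plant$time_constant)
  omega <- numeric(n); drive <- numeric(n)
  st <- pid_state()
  buf <- numeric(0)
  noise <- if (plant$noise_sd > 0) rnorm(n, 0, plant$noise_sd) else numeric(n)
  u <- 0
  for (i in seq_len(n)) {
    meas <- omega[i] + noise[i]
    buf <- c(buf, meas)
    if (length(buf) > plant$filter_window) buf <- buf[-1]
    filtered <- mean(buf)
    res <- pid_step(plant$pid, plant$setpoint - filtered, st, dt,
                    umin = 0, umax = 1, measurement = filtered)
    st <- res$state
    u <- res$output
    drive[i] <- u
    if (i < n) omega[i + 1] <- decay * omega[i] + (1 - decay) * plant$gain * u
  }
  tail10 <- seq(floor(0.9 * n) + 1L, n)
  half <- seq(floor(0.5 * n) + 1L, n)
  err <- omega - plant$setpoint
  bm_sim(t, omega, drive, rep("pid", n), kind = "stirrer",
         summary = list(setpoint = plant$setpoint,
                        final_speed = mean(omega[tail10]),
                        overshoot = max(0, max(omega) - plant$setpoint),
                        band_occupancy = mean(abs(err[half]) <= 10),
                        stabilization_time = settle_time(t, abs(err) <= 10)))
}

#' Trailing moving-average filter
#'
#' Mean of the last `window` samples; the first `window - 1` outputs average
#' the partial history available, so output and input have equal length. This
#' is the denoising filter applied to the pH and encoder readings before their
#' controllers.
#'
#' @param series numeric vector.
#' @param window window size (integer >= 1).
#' @return filtered vector, same length as `series`.
#' @examples
#' moving_average(c(1, 2, 3, 4), 2)  # 1.0 1.5 2.5 3.5
#' @export
moving_average <- function(series, window) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 || window != round(window))
    stop_config("window must be an integer >= 1")
  n <- length(series)
  if (n == 0) return(numeric(0))
  cs <- cumsum(series)
  w <- as.integer(window)
  out <- numeric(n)
  full <- seq_len(n) >= w
  out[!full] <- cs[!full] / seq_len(n)[!full]
  if (any(full)) {
    i <- which(full)
    out[i] <- (cs[i] - c(0, cs)[i - w + 1L]) / w
  }
  out
}

## ---- TimeSeries container -------------------------------------------------

#' Simulation time-series container
#'
#' All simulators return a `bm_sim`: a data frame with columns `t` (s, fixed
#' step, starting at 0), `value` (the controlled variable), `actuator` (the
#' control signal) and `mode` (phase label), plus a `summary` attribute of
#' loop-level statistics.
#'
#' @param t,value,actuator,mode equal-length columns.
#' @param kind short label of the producing simulator.
#' @param summary named list of summary statistics.
#' @return object of class `bm_sim` (inherits `data.frame`).
#' @name bm_sim
#' @export
bm_sim <- function(t, value, actuator, mode, kind, summary = list()) {
  stopifnot(length(t) == length(value), length(t) == length(actuator),
            length(t) == length(mode))
  out <- data.frame(t = t, value = value, actuator = actuator, mode = mode,
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- kind
  attr(out, "summary") <- summary
  class(out) <- c("bm_sim", "data.frame")
  out
}

#' @export
print.bm_sim <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<bm_sim:%s> %d samples, t = 0 .. %g s\n",
              attr(x, "kind"), nrow(x), x$t[nrow(x)]))
  if (length(s))
    cat(paste0("  ", names(s), " = ",
               vapply(s, function(v) format(v, digits = 4), ""), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.bm_sim <- function(object, ...) {
  s <- attr(object, "summary")
  s$kind <- attr(object, "kind")
  s$n <- nrow(object)
  class(s) <- "summary.bm_sim"
  s
}

#' @export
print.summary.bm_sim <- function(x, ...) {
  cat(sprintf("Simulation summary (%s, %d samples)\n", x$kind, x$n))
  for (nm in setdiff(names(x), c("kind", "n")))
    cat(sprintf("  %-20s %s\n", nm, format(x[[nm]], digits = 5)))
  invisible(x)
}

#' @export
plot.bm_sim <- function(x, ...) {
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(x$t, x$value, type = "l", xlab = "t (s)", ylab = "value",
       main = attr(x, "kind"), ...)
  s <- attr(x, "summary")
  if (!is.null(s$setpoint)) abline(h = s$setpoint, lty = 3)
  par(new = TRUE)
  plot(x$t, x$actuator, type = "l", col = "grey50", axes = FALSE,
       xlab = "", ylab = "")
  axis(4, col.axis = "grey40")
  invisible(x)
}
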