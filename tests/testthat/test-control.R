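test_that("pid_step implements the positional form with trapezoidal integral", {
  s <- pid_state()
  expect_equal(pid_step(pid_gains(2, 0, 0), 1.5, s, 1)$output, 3.0)
  expect_equal(pid_step(pid_gains(1, 1, 1), 0, s, 1)$output, 0)

  # constant unit error integrated over 100 s with ki = 0.0033
  g <- pid_gains(0, 0.0033, 0)
  st <- pid_state()
  u <- NA
  for (i in 1:100) { r <- pid_step(g, 1, st, 1); st <- r$state; u <- r$output }
  expect_equal(u, 0.33, tolerance = 1e-9)

  # anti-windup: the integral holds while the output is pinned
  g2 <- pid_gains(0, 1, 0)
  st <- pid_state()
  for (i in 1:50) { r <- pid_step(g2, 1, st, 1, umin = 0, umax = 2); st <- r$state }
  expect_lte(st$integral, 2 + 1)   # bounded, not 50
  r <- pid_step(g2, -1, st, 1, umin = 0, umax = 2)
  r <- pid_step(g2, -1, r$state, 1, umin = 0, umax = 2)
  expect_lt(r$state$integral, st$integral)  # unwinds once the error reverses
})

test_that("fopdt_response reproduces the analytic step response", {
  pl <- fopdt_plant(gain = 1.475, time_constant = 990, dead_time = 120, ambient = 25)
  ts <- fopdt_response(pl, 40, t_end = 6000, dt = 1)
  final <- 1.475 * 40
  want <- fopdt_step_oracle(1.475, 990, 120, 40, ts$t)
  expect_lt(max(abs((ts$value - 25) - want)), 0.001 * final)

  # dead time: identically zero response before theta
  expect_true(all(ts$value[ts$t <= 120] == 25))
  # first-order 63.2% point at theta + tau
  i <- which.min(abs(ts$t - (120 + 990)))
  expect_equal((ts$value[i] - 25) / final, 1 - exp(-1), tolerance = 1e-3)

  # halving dt halves the (already tiny) discretization error at a fixed time:
  # the update is exact for this piecewise-constant input, so both are ~0
  ts2 <- fopdt_response(pl, 40, t_end = 6000, dt = 0.5)
  want2 <- fopdt_step_oracle(1.475, 990, 120, 40, ts2$t)
  expect_lt(max(abs((ts2$value - 25) - want2)), 0.001 * final)

  expect_error(fopdt_response(pl, 40, 1000, 200), class = "magbior_config_error")
})

test_that("three-mode temperature controller obeys its mode contract", {
  pl <- fopdt_plant()
  sim <- simulate_temperature(pl, temp_control_config(35), t_end = 6000, dt = 1)

  # applied voltage bounded by the line; heater off at or above the setpoint
  expect_true(all(sim$actuator >= 0 & sim$actuator <= 120))
  expect_true(all(sim$actuator[sim$value >= 35] == 0))

  # mode 1 -> 2 handover at 20% of the commanded change, within one duty
  # period (the controller refreshes once per 5 s period)
  i_cross <- min(which(sim$value >= 25 + 0.2 * 10))
  i_pid <- min(which(sim$mode != "full-power"))
  expect_gte(i_pid, i_cross)
  expect_lte(i_pid - i_cross, 5)

  # setpoint at ambient: mode 1 is never entered, heater stays off
  sim0 <- simulate_temperature(pl, temp_control_config(25), t_end = 600, dt = 1)
  expect_false(any(sim0$mode == "full-power"))
  expect_true(all(sim0$actuator == 0))

  expect_error(simulate_temperature(pl, temp_control_config(20), 600, 1),
               class = "magbior_config_error")
})

test_that("pH chemistry matches the charge-balance oracle", {
  # one 3-second acid pulse into 1 L at pH 7: 3 drops x 50 uL x 0.47 M
  plant <- ph_plant(1, 7, c(4.05, 4.25), noise_sd = 0)
  sim <- simulate_ph(plant, t_end = 60)
  s <- attr(sim, "summary")
  expect_equal(s$drops_acid, 3)
  expect_equal(s$drops_base, 0)
  moles <- 3 * 5e-5 * 0.47
  vol <- 1 + 3 * 5e-5
  expect_equal(s$final_ph, ph_oracle(moles / vol), tolerance = 1e-9)
  expect_equal(s$final_ph, 4.15, tolerance = 0.005)

  # starting inside the band: nothing is dispensed
  quiet <- simulate_ph(ph_plant(1, 7, c(6.5, 7.5), noise_sd = 0), 60)
  expect_true(all(quiet$actuator == 0))
  expect_equal(attr(quiet, "summary")$events, 0)

  # pH only moves while dispensing; drop counts are whole numbers
  dispensed_at <- sim$mode[-nrow(sim)] %in% c("acid", "base")
  expect_true(all(diff(sim$value)[!dispensed_at] == 0))
  expect_true(all(sim$actuator == round(sim$actuator)))

  # determinism under a fixed seed
  a <- simulate_ph(ph_plant(3, 6, c(7, 8)), 900, seed = 7)
  b <- simulate_ph(ph_plant(3, 6, c(7, 8)), 900, seed = 7)
  expect_identical(a, b)
})

test_that("stirrer loop settles and is deterministic under a seed", {
  quiet <- stirrer_plant(50, noise_sd = 0)
  sim <- simulate_stirrer(quiet, t_end = 20)
  expect_lte(abs(attr(sim, "summary")$final_speed - 50), 10)
  expect_true(all(sim$actuator >= 0 & sim$actuator <= 1))

  still <- simulate_stirrer(stirrer_plant(0, noise_sd = 0), t_end = 2)
  expect_true(all(still$value == 0))
  expect_true(all(still$actuator == 0))

  a <- simulate_stirrer(stirrer_plant(50), t_end = 5, seed = 3)
  b <- simulate_stirrer(stirrer_plant(50), t_end = 5, seed = 3)
  expect_identical(a, b)
  c_ <- simulate_stirrer(stirrer_plant(50), t_end = 5, seed = 4)
  expect_false(identical(a$value, c_$value))
})

test_that("moving average uses a trailing window with partial start", {
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1, 1.5, 2.5, 3.5))
  x <- rnorm(50)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(3, 10), 4), rep(3, 10))
  # matches an explicit loop on random input
  w <- 7
  want <- vapply(seq_along(x), function(i) mean(x[max(1, i - w + 1):i]), 0)
  expect_equal(moving_average(x, w), want)
  expect_error(moving_average(x, 0), class = "magbior_config_error")
})
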