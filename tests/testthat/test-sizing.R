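test_that("AWG table is internally consistent", {
  tab <- awg_table()
  expect_equal(nrow(tab), 17)
  # resistance and mass both derive from the same cross-section
  area <- pi * tab$bare_diameter_m^2 / 4
  expect_equal(tab$resistance_per_m, 1.724e-8 / area, tolerance = 1e-12)
  expect_equal(tab$linear_mass_kg_m, 8960 * area, tolerance = 1e-12)
  # diameters shrink as the gauge number grows
  expect_true(all(diff(tab$bare_diameter_m) < 0))
  expect_error(awg_gauge(40), class = "magbior_config_error")
})

test_that("a third of a pound of 20 AWG carries 10 A at about 10.8 V", {
  req <- wire_requirements(awg_gauge(20), 0.45359237 / 3, 10)
  expect_equal(req$voltage, 10.82, tolerance = 0.01)
  expect_equal(req$power, req$voltage * 10, tolerance = 1e-12)

  # linear scalings
  req2 <- wire_requirements(awg_gauge(20), 2 * 0.45359237 / 3, 10)
  expect_equal(req2$resistance, 2 * req$resistance)
  expect_equal(req2$voltage, 2 * req$voltage)
  req0 <- wire_requirements(awg_gauge(20), 0.45359237 / 3, 0)
  expect_equal(req0$voltage, 0)
  expect_equal(req0$power, 0)
})

test_that("gauge selection picks the thinnest feasible wire", {
  m <- 0.45359237 / 3
  expect_equal(select_gauge(c(16, 18, 20, 22), m, 10, 15)$awg, 20L)
  # order invariance
  expect_equal(select_gauge(c(22, 16, 20, 18), m, 10, 15)$awg, 20L)
  # no voltage limit: the smallest diameter always wins
  expect_equal(select_gauge(c(16, 18, 20, 22), m, 10, Inf)$awg, 22L)
  # infeasible: error names the closest candidate
  expect_error(select_gauge(c(20, 22), m, 10, 1), "closest is 20 AWG",
               class = "magbior_config_error")
})

test_that("heater power follows the sensible-heat balance", {
  expect_equal(heater_power(heater_spec(2500, 25, 50, 300)), 870.97, tolerance = 1e-4)
  expect_equal(heater_power(heater_spec(2500, 30, 30, 300)), 0)
  expect_equal(heater_power(heater_spec(2500, 25, 50, 150)),
               2 * heater_power(heater_spec(2500, 25, 50, 300)))
  expect_error(heater_spec(2500, 50, 25, 300), class = "magbior_config_error")
})

test_that("impeller Reynolds number and power draw", {
  ms <- mixing_spec(1000, 0.001, 0.1, 100)       # water, 10 cm, 100 RPM
  re <- reynolds(ms)
  expect_equal(re$Re, 1000 * (100 / 60) * 0.01 / 0.001)
  expect_equal(re$regime, "turbulent")
  expect_equal(impeller_power(ms), 5 * 1000 * (100 / 60)^3 * 0.1^5)

  expect_equal(reynolds(mixing_spec(1000, 0.001, 0.1, 0))$Re, 0)
  expect_equal(suppressWarnings(impeller_power(mixing_spec(1000, 0.001, 0.1, 0))), 0)
  # Re scales with the square of the impeller diameter
  expect_equal(reynolds(mixing_spec(1000, 0.001, 0.2, 100))$Re, 4 * re$Re)
  # rev/s input path
  expect_equal(impeller_power(mixing_spec(1000, 0.001, 0.1, 2, rpm = FALSE)),
               0.40, tolerance = 1e-12)
  expect_warning(impeller_power(mixing_spec(1000, 0.5, 0.1, 100)), "turbulent")
})
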