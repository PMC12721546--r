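test_that("plane_field_map grids are complete and self-consistent", {
  pr <- biomag1_preset()
  fm <- plane_field_map(pr$array, 0.10, extent = 0.16, n = 11)
  expect_equal(dim(fm$magnitude), c(11, 11))
  expect_equal(fm$magnitude, sqrt(fm$bx^2 + fm$by^2 + fm$bz^2))
  expect_equal(fm$max, max(fm$magnitude))
  expect_equal(fm$mean, mean(fm$magnitude))
  df <- as.data.frame(fm)
  expect_equal(nrow(df), 121)
  expect_true(all(df$z_m == 0.10))

  expect_error(plane_field_map(pr$array, 0), class = "magbior_config_error")
  expect_error(plane_field_map(pr$array, 0.1, n = 1), class = "magbior_config_error")
})

test_that("field maps weaken with height above the array", {
  pr <- biomag1_preset()
  maxima <- vapply(c(0.01, 0.05, 0.10), function(z)
    plane_field_map(pr$array, z, extent = 0.16, n = 21)$max, 0)
  expect_true(all(diff(maxima) < 0))
})

test_that("axis profiles decay monotonically and carry the saturation flag", {
  pr <- biomag1_preset()
  ap <- axis_profile(pr$electromagnet, 0.10, n_points = 40)
  expect_true(all(diff(ap$bz) < 0))
  expect_true(all(diff(ap$z) > 0))
  expect_true(ap$saturated)

  # the same design-stage winding on a 7 cm former does not saturate
  expect_true(axis_profile(design_stage_em(0.05), 0.1, 10)$saturated)
  expect_false(axis_profile(design_stage_em(0.07), 0.1, 10)$saturated)

  # no current, no field
  em0 <- electromagnet(winding_spec(0.05, 0.04, 50, 0.9e-3, 0),
                       core_spec(0.05, 0.04))
  ap0 <- axis_profile(em0, 0.1, 10)
  expect_true(all(ap0$bz == 0))
})

test_that("radius_sweep turn counts follow the wire budget", {
  core <- core_spec(0.05, 0.04)
  g20 <- awg_gauge(20)
  radii <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07)
  sw <- radius_sweep(radii, 0.33 * 0.45359237, g20, 10, core, n_points = 5)
  turns <- vapply(sw, `[[`, 0L, "turns")
  expect_true(all(diff(turns) <= 0))             # fixed wire length

  sw2 <- radius_sweep(radii, 2 * 0.33 * 0.45359237, g20, 10, core, n_points = 5)
  turns2 <- vapply(sw2, `[[`, 0L, "turns")
  expect_true(all(abs(turns2 - 2 * turns) <= 1)) # doubling the budget doubles N

  # small radii decay fastest along z (normalized profiles cross below 1)
  bz_rel <- vapply(sw[c(1, 5)], function(p) p$bz[length(p$bz)] / p$bz[1], 0)
  expect_lt(bz_rel[1], bz_rel[2])

  expect_error(radius_sweep(5, 0.01, g20, 10, core), class = "magbior_config_error")
})
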