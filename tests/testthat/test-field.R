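test_that("loop_field matches the Biot-Savart line-integral oracle", {
  set.seed(42)
  for (i in 1:10) {
    a <- runif(1, 0.01, 0.10)
    I <- runif(1, 1, 10)
    # random point, kept a few mm off the filament
    repeat {
      p <- c(runif(2, -0.12, 0.12), runif(1, -0.1, 0.1))
      if (sqrt((sqrt(p[1]^2 + p[2]^2) - a)^2 + p[3]^2) > 0.005) break
    }
    got <- loop_field(loop_source(a, I), p)
    want <- bs_loop_oracle(a, I, p)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("loop field closed forms and symmetries hold", {
  lp <- loop_source(0.05, 1)
  B0 <- loop_field(lp, point3(0, 0, 0))
  expect_equal(unname(B0), c(0, 0, 4e-7 * pi / (2 * 0.05)), tolerance = 1e-12)

  # mirror symmetry of a planar loop: z -> -z flips the transverse components
  p <- c(0.03, 0.01, 0.02)
  up <- loop_field(loop_source(0.05, 10), p)
  dn <- loop_field(loop_source(0.05, 10), c(p[1], p[2], -p[3]))
  expect_equal(unname(up["bz"]), unname(dn["bz"]), tolerance = 1e-14)
  expect_equal(unname(up[c("bx", "by")]), -unname(dn[c("bx", "by")]), tolerance = 1e-14)

  # the off-axis kernel converges to the on-axis closed form as rho -> 0
  for (z in c(0.01, 0.05, 0.2)) {
    near <- loop_field(loop_source(0.05, 7), c(1e-9, 0, z))
    expect_equal(unname(near["bz"]), axis_field_oracle(0.05, 7, z), tolerance = 1e-9)
    expect_lt(abs(near["bx"]), 1e-12)
  }

  expect_error(loop_field(loop_source(0.05, 1), c(0.05, 0, 0)),
               class = "magbior_domain_error")
})

test_that("build_winding lays turns into layers and conserves the count", {
  w1 <- build_winding(winding_spec(0.02, 0.01, 1, 0.9e-3, 1))
  expect_equal(nrow(w1), 1)
  expect_equal(w1$radius, 0.02 + 0.45e-3)

  w <- build_winding(winding_spec(0.05, 0.04, 300, 0.9e-3, 10 / 3))
  expect_equal(nrow(w), 300)                         # conservation
  per_layer <- floor(0.04 / 0.9e-3)
  expect_equal(per_layer, 44)
  expect_equal(length(unique(w$radius)), 7)          # ceil(300/44) layers
  expect_equal(sum(w$radius == max(w$radius)), 300 - 6 * 44)  # last layer partial
  expect_true(all(w$radius >= 0.05))
  expect_true(all(w$z >= -0.04 & w$z <= 0))

  for (n in c(2, 45, 113)) {
    wn <- build_winding(winding_spec(0.03, 0.02, n, 0.8e-3, 2))
    expect_equal(nrow(wn), n)
  }
  expect_error(winding_spec(0.05, 0.0005, 10, 0.9e-3, 1),
               class = "magbior_config_error")
})

test_that("coil_field superposes linearly and matches the thin-coil closed form", {
  expect_equal(unname(coil_field(list(), point3(0, 0, 0.1))), c(0, 0, 0))

  spec <- winding_spec(0.05, 0.04, 300, 0.9e-3, 10 / 3)
  w <- build_winding(spec)
  p <- point3(0.02, 0.01, 0.05)
  B1 <- coil_field(w, p)
  w2 <- w; w2$current <- 2 * w2$current
  expect_equal(unname(coil_field(w2, p)), 2 * unname(B1), tolerance = 1e-14)

  # at z = 10 cm the full winding is within 5% of a thin coil of the mean
  # turn radius placed at the winding mid-plane
  Bz <- coil_field(w, point3(0, 0, 0.10))[["bz"]]
  d <- 0.10 + 0.02                       # distance to the winding mid-plane
  a_mean <- mean(w$radius)
  thin <- 4e-7 * pi * 300 * (10 / 3) * a_mean^2 / (2 * (a_mean^2 + d^2)^1.5)
  expect_lt(abs(Bz - thin) / thin, 0.05)

  # evaluation within one wire diameter of a filament is refused
  expect_error(coil_field(w, c(0.0505, 0, -0.002)), class = "magbior_domain_error")
})
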