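test_that("core magnetization is linear below saturation and capped above", {
  core <- core_spec(0.05, 0.04, 200, 2.16)

  z0 <- core_magnetization(core, 0)
  expect_equal(z0$M, 0)
  expect_equal(z0$moment, 0)

  cm <- core_magnetization(core, 1e3)
  expect_equal(cm$M, 199 * 1e3)
  expect_equal(cm$moment, 199e3 * pi * 0.05^2 * 0.04)
  expect_false(cm$saturated)

  sat <- core_magnetization(core, 1e5)
  expect_equal(sat$M, 2.16 / (4e-7 * pi), tolerance = 1e-12)
  expect_true(sat$saturated)
})

test_that("dipole axis field follows the inverse-cube law", {
  expect_equal(dipole_axis_field(540, 0.12), 0.0625, tolerance = 1e-6)
  expect_equal(dipole_axis_field(10, 0.2) / dipole_axis_field(10, 0.4), 8)
  expect_error(dipole_axis_field(10, 0), class = "magbior_domain_error")
  expect_error(dipole_axis_field(10, -0.1), class = "magbior_domain_error")

  # far-field equivalence: a loop with N I A = m approaches the dipole form
  a <- 0.05; m <- 540
  I_eq <- m / (pi * a^2)
  loopBz <- loop_field(loop_source(a, I_eq), point3(0, 0, 1))[["bz"]]
  expect_lt(abs(loopBz - dipole_axis_field(m, 1)) / dipole_axis_field(m, 1), 0.005)
})

test_that("amplification gain caps the pole-face reference field at saturation", {
  # construct windings whose concentrated pole-face reference hits set values
  em_with_bref <- function(b_target) {
    a <- 0.05; pitch <- 0.9e-3; N <- 100
    a1 <- a + pitch / 2
    I <- b_target * 2 * a1 / (4e-7 * pi * N)
    electromagnet(winding_spec(a, 0.04, N, pitch, I), core_spec(a, 0.04, 200, 2.16))
  }
  expect_equal(core_amplification(em_with_bref(0.02)), 108)     # 2.16 / 0.02
  expect_equal(core_amplification(em_with_bref(0.005)), 200)    # unsaturated
  expect_true(is_saturated(em_with_bref(0.02)))
  expect_false(is_saturated(em_with_bref(0.005)))

  # once saturated, g is non-increasing in current and g * B_ref stays at b_sat
  brefs <- seq(0.012, 0.05, by = 0.004)
  g <- vapply(brefs, function(b) core_amplification(em_with_bref(b)), 0)
  expect_true(all(diff(g) < 0))
  expect_equal(g * brefs, rep(2.16, length(brefs)), tolerance = 1e-9)

  # zero current: g = mu_r by convention
  em0 <- electromagnet(winding_spec(0.05, 0.04, 100, 0.9e-3, 0),
                       core_spec(0.05, 0.04, 200, 2.16))
  expect_equal(core_amplification(em0), 200)
})

test_that("electromagnet field reduces to the bare coil for an air core", {
  w <- winding_spec(0.05, 0.04, 50, 0.9e-3, 2)
  em_air <- electromagnet(w, core_spec(0.05, 0.04, mu_r = 1, b_sat = 2.16))
  p <- point3(0.02, -0.01, 0.03)
  expect_equal(unname(electromagnet_field(em_air, p)),
               unname(coil_field(build_winding(w), p)), tolerance = 1e-12)
})

test_that("reference electromagnet meets the saturation bound and near-field strength", {
  pr <- biomag1_preset()
  em <- pr$electromagnet
  expect_lte(sqrt(sum(electromagnet_field(em, point3(0, 0, 0))^2)), 2.16)
  expect_gt(electromagnet_field(em, point3(0, 0, 0.01))[["bz"]], 1.0)

  # pole-face cap: the core top face (clear of the winding filaments by the
  # one-wire-diameter evaluation policy) never exceeds b_sat
  g <- expand.grid(r = seq(0, 0.049, length.out = 8),
                   th = seq(0, 2 * pi, length.out = 13)[-13])
  B <- electromagnet_field(em, cbind(g$r * cos(g$th), g$r * sin(g$th), 0))
  expect_lt(max(sqrt(rowSums(B^2))), 2.16 + 1e-9)
})

test_that("the field is numerically divergence-free", {
  pr <- biomag1_preset()
  em <- pr$electromagnet
  h <- 1e-4
  for (p in list(c(0.02, 0.01, 0.03), c(0, 0.04, 0.06), c(-0.03, 0.02, 0.02))) {
    div <- (electromagnet_field(em, p + c(h, 0, 0))[["bx"]] -
            electromagnet_field(em, p - c(h, 0, 0))[["bx"]] +
            electromagnet_field(em, p + c(0, h, 0))[["by"]] -
            electromagnet_field(em, p - c(0, h, 0))[["by"]] +
            electromagnet_field(em, p + c(0, 0, h))[["bz"]] -
            electromagnet_field(em, p - c(0, 0, h))[["bz"]]) / (2 * h)
    magB <- sqrt(sum(electromagnet_field(em, p)^2))
    expect_lt(abs(div), 1e-6 * magB / h)
  }
})

test_that("array superposition, symmetry and antisymmetry", {
  pr <- biomag1_preset()
  em <- pr$electromagnet
  one <- em_array(em)
  p <- point3(0.01, 0.02, 0.05)
  expect_equal(unname(array_field(one, p)), unname(electromagnet_field(em, p)))

  # |B| invariant under 120-degree rotation about the centroid axis
  arr <- pr$array
  rot <- function(p, ang) c(cos(ang) * p[1] - sin(ang) * p[2],
                            sin(ang) * p[1] + cos(ang) * p[2], p[3])
  for (p in list(c(0.03, 0.01, 0.02), c(-0.02, 0.05, 0.08), c(0.06, 0, 0.04))) {
    m0 <- sqrt(sum(array_field(arr, p)^2))
    m1 <- sqrt(sum(array_field(arr, rot(p, 2 * pi / 3))^2))
    expect_lt(abs(m0 - m1), 1e-12)
  }

  # equal and opposite coaxial units cancel exactly on the shared axis
  w <- winding_spec(0.05, 0.04, 50, 0.9e-3, 2)
  wneg <- winding_spec(0.05, 0.04, 50, 0.9e-3, -2)
  core <- core_spec(0.05, 0.04, 200, 2.16)
  pair <- em_array(electromagnet(w, core), electromagnet(wneg, core))
  expect_equal(unname(array_field(pair, point3(0, 0, 0.05))), c(0, 0, 0))

  # linearity below saturation: scaling every current scales the field
  w1 <- winding_spec(0.05, 0.04, 20, 0.9e-3, 0.1)   # far below saturation
  w3 <- winding_spec(0.05, 0.04, 20, 0.9e-3, 0.3)
  e1 <- electromagnet(w1, core); e3 <- electromagnet(w3, core)
  expect_equal(3 * unname(electromagnet_field(e1, p)),
               unname(electromagnet_field(e3, p)), tolerance = 1e-12)
})
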