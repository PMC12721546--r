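test_that("complete elliptic integrals match direct quadrature", {
  K_quad <- function(m) integrate(function(th) 1 / sqrt(1 - m * sin(th)^2),
                                  0, pi / 2, rel.tol = 1e-12)$value
  E_quad <- function(m) integrate(function(th) sqrt(1 - m * sin(th)^2),
                                  0, pi / 2, rel.tol = 1e-12)$value
  for (m in c(0, 0.1, 0.5, 0.9, 0.999)) {
    ke <- elliptic_ke(m)
    expect_equal(ke$K, K_quad(m), tolerance = 1e-10)
    expect_equal(ke$E, E_quad(m), tolerance = 1e-10)
  }
  ke0 <- elliptic_ke(0)
  expect_identical(ke0$K, pi / 2)
  expect_identical(ke0$E, pi / 2)
  # frozen quadrature values at m = 0.5
  ke5 <- elliptic_ke(0.5)
  expect_equal(ke5$K, 1.8540747, tolerance = 1e-7)
  expect_equal(ke5$E, 1.3506439, tolerance = 1e-7)
})

test_that("K diverges and E tends to 1 as the parameter approaches 1", {
  near <- elliptic_ke(1 - 1e-12)
  expect_gt(near$K, 10)
  expect_equal(near$E, 1, tolerance = 1e-5)
  expect_error(elliptic_ke(1), class = "magbior_domain_error")
  expect_error(elliptic_ke(1.2), class = "magbior_domain_error")
  expect_error(elliptic_ke(-0.1), class = "magbior_domain_error")
})

test_that("elliptic_ke is vectorized", {
  m <- c(0, 0.25, 0.5, 0.75)
  ke <- elliptic_ke(m)
  expect_length(ke$K, 4)
  expect_equal(ke$K[3], elliptic_ke(0.5)$K)
})
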