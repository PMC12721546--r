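# Independent numerical oracles used across the tests.

MU0_TEST <- 4e-7 * pi

# Brute-force Biot-Savart line integral around a circular loop (midpoint rule
# over nseg straight segments). Independent of the elliptic-integral path.
bs_loop_oracle <- function(a, current, p, center = c(0, 0, 0), nseg = 10000) {
  th <- ((seq_len(nseg) - 0.5)) * 2 * pi / nseg
  dl <- 2 * pi * a / nseg
  sx <- center[1] + a * cos(th)
  sy <- center[2] + a * sin(th)
  tx <- -sin(th); ty <- cos(th)           # unit tangent
  rx <- p[1] - sx; ry <- p[2] - sy; rz <- p[3] - center[3]
  r3 <- (rx^2 + ry^2 + rz^2)^1.5
  k <- MU0_TEST * current / (4 * pi) * dl
  c(sum(k * ty * rz / r3),
    sum(k * (-tx) * rz / r3),
    sum(k * (tx * ry - ty * rx) / r3))
}

# closed-form on-axis field of a single loop
axis_field_oracle <- function(a, current, z) {
  MU0_TEST * current * a^2 / (2 * (a^2 + z^2)^1.5)
}

# analytic FOPDT step response (temperature above ambient)
fopdt_step_oracle <- function(K, tau, theta, u0, t) {
  ifelse(t > theta, K * u0 * (1 - exp(-(t - theta) / tau)), 0)
}

# strong acid/base charge balance pH
ph_oracle <- function(net_acid_conc, kw = 1e-14) {
  -log10((net_acid_conc + sqrt(net_acid_conc^2 + 4 * kw)) / 2)
}

# the design-stage electromagnet used in the radius charts: one third of a
# pound of 20 AWG at 10 A, core proportions 5 cm radius : 4 cm height
design_stage_em <- function(radius, current = 10, mass_lb = 0.33) {
  g <- awg_gauge(20)
  pitch <- g$bare_diameter * 1.07
  wire_length <- mass_lb * 0.45359237 / g$linear_mass
  a1 <- radius + 0.5 * pitch
  turns <- floor(wire_length / (2 * pi * a1))
  height <- 0.04 * radius / 0.05
  electromagnet(winding_spec(radius, height, turns, pitch, current),
                core_spec(radius, height, 200, 2.16))
}
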