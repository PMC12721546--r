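---
title: "Models and methods behind magbior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magbior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magbior)
```

magbior models the three physical subsystems of a magnetic-retention bench
bioreactor — the electromagnet array that holds nanoparticle-immobilized
biocatalyst in the vessel, the actuator sizing, and the temperature/pH/
stirring control loops. This vignette records the models, their assumptions,
the parameter provenance, and the design choices made where more than one
reasonable reading existed. It states no empirical result beyond what the
package's tests and acceptance script compute themselves.

## The magnetostatic model

### Loop kernel

Everything magnetic is built from the exact field of a filamentary circular
loop, written with complete elliptic integrals $K(m)$ and $E(m)$
(`elliptic_ke()`, evaluated by the arithmetic–geometric mean to machine
precision). Off axis, with $\rho^2 = x^2+y^2$, $r^2 = \rho^2+z^2$,
$\alpha^2 = a^2 + r^2 - 2a\rho$, $\beta^2 = a^2 + r^2 + 2a\rho$,
$q^2 = 1 - \alpha^2/\beta^2$ and $C = \mu_0 I/\pi$:

$$B_x = \frac{C x z}{2\alpha^2\beta\rho^2}\left[(a^2+r^2)E - \alpha^2 K\right],
\quad B_y = \frac{y}{x}B_x, \quad
B_z = \frac{C}{2\alpha^2\beta}\left[(a^2-r^2)E + \alpha^2 K\right].$$

Two numerical choices matter here. First, within $10^{-12}$ m of the axis the
code switches to the closed form $B_z = \mu_0 I a^2/2(a^2+z^2)^{3/2}$, so the
$1/\rho^2$ prefactor never divides by zero; the tests confirm the off-axis
kernel converges to this branch. Second, evaluation on the filament itself
($\alpha^2 = 0$) and — at the winding level — anywhere within one wire
diameter of a filament raises an error rather than returning a huge clamped
number: a near-filament value would be dominated by the neglected conductor
thickness, so refusing is more honest than extrapolating. The kernel is
validated against an independent brute-force Biot–Savart line integral
(10^4 segments) to below $10^{-8}$ T.

### Windings

`build_winding()` discretizes a coil specification into its turns: layers
fill vertically from the bottom of the winding at a pitch of one wire
diameter; a full layer steps the radius out by one diameter. The effective
pitch defaults to the bare AWG diameter plus a 7 % enamel allowance
(0.87–0.9 mm for 20 AWG); the layer rule is fixed, the allowance is
configurable because enamel build varies by wire class. The reference coil
(300 turns over 4 cm of 20 AWG) therefore packs 44 turns per layer in
7 layers, the last partial.

### Saturable core

The core model is deliberately simple. A cylindrical low-carbon-steel core
(assumed relative permeability $\mu_r = 200$; saturation flux density
$B_{sat} = 2.16$ T for ASTM A36 — $\mu_r$ of delivered stock varies with
supplier and heat treatment, and 200 is the standard literature estimate for
this carbon content and grain size) multiplies the bare-coil field uniformly
by

$$g = \min\!\left(\mu_r,\; \frac{B_{sat}}{B_{ref}}\right), \qquad
B_{ref} = \frac{\mu_0 N I}{2 a_1},$$

where $B_{ref}$ is the pole-face flux density of the *equivalent concentrated
$N$-turn loop* at the first-layer radius $a_1$. Below saturation the core
simply contributes its permeability; once $\mu_r B_{ref}$ would exceed
$B_{sat}$, the gain is capped so the pole-face reference field equals the
saturation point, and further current buys nothing — which is what saturation
means operationally for this device.

Two design decisions deserve an explicit record:

* **Why the concentrated-loop reference, not the distributed winding's field
  at the pole-face centre?** The distributed value is systematically smaller
  (most turns sit well below the face: 0.0094 T versus 0.0125 T for the
  reference coil), and with it the 5 cm design-stage coil would be classified
  *unsaturated* — contradicting the design chart this model exists to
  reproduce, in which 5 cm cores saturate and 6–7 cm cores do not. The
  concentrated-loop reference reproduces that split exactly and is the
  natural single-number "surface field" of the equivalent coil picture used
  to motivate the core model in the first place. The distributed evaluation
  remains available (`core_amplification(em, method = "distributed")`).
* **Pointwise clamp.** Uniform amplification alone can report more than
  $B_{sat}$ immediately next to the winding bore, where the bare field
  exceeds its on-axis value. The composite per-electromagnet field magnitude
  is therefore clamped at $B_{sat}$ (direction preserved). The clamp is
  per-electromagnet; distinct electromagnets superpose afterwards, as
  their fluxes pass through different cores.

The magnetization route of the same physics —
$M = \min(\chi_m H, B_{sat}/\mu_0)$, $m = MV$, dipole far field
$B_z = \mu_0 m/2\pi z^3$ — is implemented (`core_magnetization()`,
`dipole_axis_field()`) and used in tests as a far-field cross-check; it is
not the default field model because a point dipole badly misrepresents the
near field 1–10 cm above a 5 cm core, which is exactly the region the device
cares about.

### Arrays, maps and the design sweep

`triangular_array()` places three identical electromagnets with vertical axes
on a circle of radius $2a/\sqrt{3}$ about the vessel axis — mutually tangent
coils, the tightest packing under a 16 cm vessel; the spacing is configurable
since only "triangular" is fixed by the device. The total supply current
(10 A) splits equally across the parallel coils; `plane_field_map()` then
reports the field magnitude on horizontal planes (the design question is
whether 0.2 T survives at the 10 cm liquid surface).

`radius_sweep()` reproduces the radius-selection chart: for a fixed wire-mass
budget (0.33 lb of 20 AWG per coil at the design stage) the turn count at
radius $a$ is $N = \lfloor L / 2\pi a_1\rfloor$ with $L$ the wire length the
budget buys. A self-consistent mean-turn circumference (iterating on the
layer build-up) would be slightly more faithful for small radii, but it
breaks two properties the simple rule guarantees — $N$ non-increasing in
radius and $N$ doubling with the budget — and the chart's verdict (5 cm
saturates, 6–7 cm do not, small radii decay fastest along $z$) is identical
under both; the single-pass rule was kept.

## Sizing calculations

Heater: $P = m c_p (T_f - T_i)/\Delta t$ on 2500 g of water heated 25→50 °C
in 5 min, conduction-only. The water $c_p$ default is 4.1806 J g⁻¹ K⁻¹.
Impeller: $Re = \rho N D^2/\mu$ (speed in rev/s — the 16 670 value for water,
10 cm, 100 RPM confirms rev/s, not rad/s) with the turbulent label above the
standard stirred-tank threshold $10^4$, and $P = N_p \rho N^3 D^5$ with
$N_p = 5$ for a six-blade Rushton turbine. Wire selection: copper
resistivity $1.724\times10^{-8}\,\Omega$ m at 20 °C, density 8960 kg m⁻³,
published ASTM B258 diameters; these constants reproduce the 10.82 V
requirement for a third of a pound of 20 AWG at 10 A to 0.13 %.

## Control-loop simulators

### Temperature

The vessel is a first-order-plus-dead-time plant
$G(s) = K e^{-\theta s}/(\tau s + 1)$ with the identified constants
$K = 1.475$ °C/V of *average applied voltage*, $\tau = 990$ s,
$\theta = 120$ s. Integration uses the exact zero-order-hold exponential
update per step, so the simulated step response matches the analytic form to
rounding error when $\theta$ is a grid multiple; `dt` must be at most
$\tau/10$.

The controller has three modes: full line voltage until the temperature has
risen 20 % of the commanded change, then PID (gains 3.3 / 0.0033 / 82.5)
modulating the relay duty cycle, and off at or above the setpoint with PID
re-engagement below it. The PID is positional with a trapezoidal integral,
derivative on measurement (no setpoint kick) and conditional-integration
anti-windup. One genuinely open interpretation had to be settled: whether
the tuned gains act on a duty *fraction* or on *volts*. Treating the output
as a duty fraction multiplies the effective loop gain by the 120 V line; a
linearized analysis then puts the loop magnitude near 38 at the −180° phase
crossing of the 120 s dead time — a saturating relay limit cycle far outside
the ±1 °C specification, which the hardware demonstrably met. The gains were
tuned in a block-diagram simulation whose plant input is the average voltage,
so the volts reading (loop magnitude ≈ 0.32, stable) is both the faithful and
the working one; it is the default, with `pid_output = "duty"` retained. The
controller refreshes once per 5 s relay period, so mode handovers quantize to
that period.

### pH

The pH loop is a band controller on timed titrant pulses: if the filtered
reading leaves the band, the corresponding drip valve opens for 3 s at
1 drop/s, then the controller waits 5 s for mixing. Chemistry is an
unbuffered strong acid/strong base charge balance on a well-mixed volume:
with net strong-acid concentration $c$, $[\mathrm{H}^+]$ solves
$[\mathrm{H}^+] - K_w/[\mathrm{H}^+] = c$. Titrants are 0.47 M HCl and
0.5 M NaOH; the drop volume is 50 µL (the standard 20-drops-per-mL drip
chamber — the hardware value is not recorded, so this is a documented
default). Moles and volume are conserved exactly and the tests check the
arithmetic against the closed-form charge balance.

A consequence worth stating: with 3-drop pulses in 3 L, one pulse moves the
net-acid concentration by $2.35\times10^{-5}$ M, comparable to the width of
an entire pH band in concentration space. The discrete titration therefore
*lands* somewhere inside the band rather than converging to its middle; in
an unbuffered medium the landing point is quantized. The real working
substance is buffered (which widens the band in concentration space and
centres the result), but buffering is explicitly outside this model's scope.
The simulator guarantees — and the tests assert — termination inside the
commanded band, for both the acid (4.5–5.5 from pH 7) and alkaline (7–8 from
pH 6) operating scenarios.

### Stirrer

The motor is first order, $\dot\omega = (G u - \omega)/\tau_m$, with drive
$u \in [0,1]$, full-drive speed $G = 130$ RPM and $\tau_m = 0.3$ s — plumbing
defaults describing a small geared DC motor rated near 100 RPM under load,
not identified constants. The PID (0.18 / 0.8 / 0.0016) acts on the encoder
reading after seeded Gaussian noise (default SD 2 RPM) and a trailing
moving-average filter (default 5 samples; the filter method is fixed by the
device, the window size is a documented default). The loop runs at 10 ms and
holds the ±10 RPM specification at 25, 50 and 100 RPM.

All simulators are deterministic given their configuration and seed; the
magnetics and sizing paths use no randomness at all.

## Problem sizes and configuration

The shipped `biomag1.yaml` preset records every reference value (geometry in
cm, currents in A) with unit-suffixed keys; `load_config()` validates each
field by name and normalizes to SI. Configuration is YAML. Field maps default
to 81 × 81 nodes over 16 × 16 cm (a few seconds per plane on one core);
the temperature loop is exercised over 20 000 s at 1 s steps, the pH loop
over 20 min at 1 s, the stirrer over 30 s at 10 ms — horizons chosen so each
loop passes well into its steady state.

## Known limitations

* No finite elements: the core acts through a uniform gain plus magnitude
  clamp, not a solved magnetization distribution; hysteresis and eddy
  currents (mitigated in hardware by the laminated core) are ignored.
* The amplification model is calibrated to the device's design semantics
  (pole-face saturation) rather than to measured field maps; absolute
  near-field values inherit the $\mu_r = 200$ assumption.
* Magnetophoretic force and particle trajectories are out of scope — the
  package maps flux density, the retention criterion being a field-magnitude
  threshold.
* The temperature plant is the identified linear model; residual-heat
  effects beyond first order plus dead time (and any cooling path other than
  loss to ambient) are absent, so simulated stabilization times are not
  hardware stabilization times.
* The pH plant is unbuffered; real fermentation media buffer strongly.
* Passing tests demonstrate internal consistency and the stated design
  values, not agreement with measurements of a physical device.
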