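## Saturable ferromagnetic core model.
##
## Two routes are provided:
##  * the default *amplification* route: the core multiplies the bare-coil
##    field uniformly by g = min(mu_r, Bsat / B_ref), where B_ref is the
##    pole-face flux density of the equivalent concentrated N-turn loop, and
##    the composite per-electromagnet field magnitude is clamped at Bsat;
##  * the *moment* route (core_magnetization + dipole_axis_field): magnetize
##    the core with the applied H, cap M at Bsat/mu0, and treat it as a point
##    dipole -- useful as a far-field cross-check.

#' Core magnetization under an applied field
#'
#' Linear magnetization `M = chi_m * H` (susceptibility `chi_m = mu_r - 1`)
#' capped at the saturation magnetization `Msat = b_sat / mu0`. The magnetic
#' dipole moment follows from the core volume, `m = M * V`.
#'
#' @param core a [core_spec()].
#' @param h_applied applied magnetic field strength H in A/m (>= 0); for a
#'   bare coil, `H = B_coil / mu0`.
#' @return list with `M` (A/m), `moment` (A m^2) and `saturated` (logical).
#' @examples
#' core_magnetization(core_spec(0.05, 0.04, 200, 2.16), 1e3)
#' @export
core_magnetization <- function(core, h_applied) {
  stopifnot(inherits(core, "core_spec"))
  check_num(h_applied, "h_applied", min = 0)
  m_sat <- core$b_sat / MU0
  M <- min((core$mu_r - 1) * h_applied, m_sat)
  list(M = M, moment = M * core$volume, saturated = M >= m_sat)
}

#' On-axis far field of a magnetic dipole
#'
#' \eqn{B_z = \mu_0 m / (2 \pi z^3)}: the axial field of a point dipole of
#' moment `m`, which is also the large-z limit of any coil with the same
#' ampere-turns-area product `N I A = m`.
#'
#' @param moment magnetic dipole moment in A m^2.
#' @param z axial distance in metres (> 0).
#' @return axial flux density in tesla.
#' @examples
#' dipole_axis_field(540, 0.12)  # 0.0625 T
#' @export
dipole_axis_field <- function(moment, z) {
  check_num(moment, "moment")
  check_num(z, "z", len = NA)
  if (any(z <= 0)) stop_domain("dipole_axis_field requires z > 0")
  MU0 * moment / (2 * pi * z^3)
}

## Pole-face reference flux density of the bare winding.
## "concentrated": equivalent N-turn loop at the first-layer radius, evaluated
## at its centre: B_ref = mu0 N I / (2 a1). "distributed": |coil_field| of the
## layered winding at the pole-face centre (0, 0, 0).
surface_field <- function(em, method = c("concentrated", "distributed")) {
  method <- match.arg(method)
  w <- em$winding
  if (method == "concentrated") {
    a1 <- w$inner_radius + 0.5 * w$wire_diameter
    abs(MU0 * w$turns * w$current / (2 * a1))
  } else {
    B <- coil_field(build_winding(w), point3(0, 0, 0), min_clearance = 0)
    sqrt(sum(B^2))
  }
}

#' Saturable-core amplification gain
#'
#' The core multiplies the bare-coil field by its relative permeability until
#' the pole-face flux density would exceed the material's saturation point;
#' beyond that the gain is reduced so the pole-face reference field equals
#' `b_sat`:
#' \deqn{g = \min(\mu_r,\; B_{sat} / B_{ref})}
#' `B_ref` is the pole-face flux density of the bare winding. By default it is
#' evaluated for the equivalent concentrated N-turn loop at the pole face,
#' \eqn{B_{ref} = \mu_0 N I / (2 a)}; `method = "distributed"` instead
#' evaluates the layered winding at the pole-face centre (a smaller value,
#' since most turns sit below the face). With zero current `g = mu_r` by
#' convention.
#'
#' @param em an [electromagnet()].
#' @param method how the pole-face reference field is evaluated (see Details).
#' @return dimensionless gain `g` with `g * B_ref <= b_sat`.
#' @seealso [is_saturated()], [electromagnet_field()]
#' @export
core_amplification <- function(em, method = c("concentrated", "distributed")) {
  stopifnot(inherits(em, "electromagnet"))
  b_ref <- surface_field(em, method)
  if (b_ref == 0) return(em$core$mu_r)
  min(em$core$mu_r, em$core$b_sat / b_ref)
}

#' Is the electromagnet's core saturated?
#'
#' TRUE when the amplification gain is capped below `mu_r`, i.e. the material
#' cannot supply the full permeability-driven flux.
#'
#' @inheritParams core_amplification
#' @return logical.
#' @export
is_saturated <- function(em, method = c("concentrated", "distributed")) {
  core_amplification(em, method) < em$core$mu_r - 1e-12
}

#' Field of a complete electromagnet (winding + saturable core)
#'
#' The default `"amplified"` model scales the exact bare-winding field by the
#' saturation-capped gain of [core_amplification()] and clamps the resulting
#' magnitude at `b_sat` pointwise (direction preserved), so no point --
#' including the pole face next to the winding bore -- reports more flux than
#' the core material can carry. `model = "bare"` returns the air-core winding
#' field.
#'
#' @param em an [electromagnet()].
#' @param p evaluation point(s) in global coordinates (see [point3()]).
#' @param model `"amplified"` (default) or `"bare"`.
#' @param method reference-field evaluation passed to [core_amplification()].
#' @return field vector(s) in tesla, as in [loop_field()].
#' @examples
#' em <- electromagnet(winding_spec(0.05, 0.04, 300, 0.9e-3, 10 / 3), core_spec(0.05, 0.04))
#' electromagnet_field(em, point3(0, 0, 0.01))
#' @export
electromagnet_field <- function(em, p, model = c("amplified", "bare"),
                                method = c("concentrated", "distributed")) {
  stopifnot(inherits(em, "electromagnet"))
  model <- match.arg(model)
  pts <- as_points(p)
  local <- cbind(pts[, 1] - em$center[1], pts[, 2] - em$center[2], pts[, 3] - em$center[3])
  B <- coil_field(build_winding(em$winding), local)
  if (!is.matrix(B)) B <- matrix(B, 1, 3, dimnames = list(NULL, c("bx", "by", "bz")))
  if (model == "amplified") {
    g <- core_amplification(em, method)
    B <- g * B
    mag <- sqrt(rowSums(B^2))
    over <- mag > em$core$b_sat
    if (any(over)) B[over, ] <- B[over, , drop = FALSE] * (em$core$b_sat / mag[over])
  }
  if (nrow(B) == 1) B[1, ] else B
}

#' Field of an electromagnet array
#'
#' Vector sum of [electromagnet_field()] over the array elements, each
#' evaluated in its own centred frame.
#'
#' @param array an [em_array()].
#' @param p evaluation point(s) in global coordinates.
#' @inheritParams electromagnet_field
#' @return field vector(s) in tesla.
#' @export
array_field <- function(array, p, model = c("amplified", "bare"),
                        method = c("concentrated", "distributed")) {
  stopifnot(inherits(array, "em_array"))
  pts <- as_points(p)
  B <- matrix(0, nrow(pts), 3, dimnames = list(NULL, c("bx", "by", "bz")))
  for (em in array$electromagnets) {
    Bi <- electromagnet_field(em, pts, model = model, method = method)
    if (!is.matrix(Bi)) Bi <- matrix(Bi, 1, 3)
    B <- B + Bi
  }
  if (nrow(B) == 1) B[1, ] else B
}
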