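## Off-axis field of circular loops, layered windings, and their superposition.
##
## In loop-centred cylindrical quantities (rho^2 = x^2 + y^2,
## r^2 = rho^2 + z^2, alpha^2 = a^2 + r^2 - 2 a rho,
## beta^2 = a^2 + r^2 + 2 a rho, q^2 = 1 - alpha^2/beta^2, C = mu0 I / pi):
##
##   Bx = C x z / (2 alpha^2 beta rho^2) [ (a^2 + r^2) E(q^2) - alpha^2 K(q^2) ]
##   By = (y / x) Bx
##   Bz = C     / (2 alpha^2 beta)       [ (a^2 - r^2) E(q^2) + alpha^2 K(q^2) ]
##
## with the on-axis closed form Bz = mu0 I a^2 / (2 (a^2 + z^2)^{3/2}) at rho = 0.

ON_AXIS_TOL <- 1e-12   # rho below this uses the closed-form axis branch

## Vectorized kernel: field of one loop (radius a, current I, centred at the
## origin of the supplied coordinates) at n points. Returns an n x 3 matrix.
loop_field_kernel <- function(a, I, x, y, z) {
  rho2 <- x^2 + y^2
  r2 <- rho2 + z^2
  rho <- sqrt(rho2)
  alpha2 <- a^2 + r2 - 2 * a * rho
  if (any(alpha2 <= .Machine$double.eps * a^2))
    stop_domain("field requested on the loop filament (singular)")
  beta <- sqrt(a^2 + r2 + 2 * a * rho)
  q2 <- 1 - alpha2 / beta^2
  B <- matrix(0, length(x), 3, dimnames = list(NULL, c("bx", "by", "bz")))
  off <- rho > ON_AXIS_TOL
  if (any(off)) {
    ke <- elliptic_ke(q2[off])
    C <- MU0 * I / pi
    tr <- C * z[off] / (2 * alpha2[off] * beta[off] * rho2[off]) *
      ((a^2 + r2[off]) * ke$E - alpha2[off] * ke$K)
    B[off, 1] <- x[off] * tr
    B[off, 2] <- y[off] * tr
    B[off, 3] <- C / (2 * alpha2[off] * beta[off]) *
      ((a^2 - r2[off]) * ke$E + alpha2[off] * ke$K)
  }
  if (any(!off))
    B[!off, 3] <- MU0 * I * a^2 / (2 * (a^2 + z[!off]^2)^1.5)
  B
}

#' Magnetic flux density of a single circular loop
#'
#' Exact off-axis solution of a filamentary circular loop through complete
#' elliptic integrals; on the axis the closed form
#' \eqn{B_z = \mu_0 I a^2 / (2 (a^2 + z^2)^{3/2})} is used so that no division
#' by the cylindrical radius occurs.
#'
#' @param loop a [loop_source()].
#' @param p evaluation point(s): a [point3()], length-3 numeric, or an
#'   `n x 3` matrix of coordinates in metres.
#' @return a numeric vector `c(bx, by, bz)` in tesla for a single point, or an
#'   `n x 3` matrix for multiple points.
#' @examples
#' loop_field(loop_source(0.05, 1), point3(0, 0, 0))  # (0, 0, mu0/(2a))
#' @export
loop_field <- function(loop, p) {
  stopifnot(inherits(loop, "loop_source"))
  pts <- as_points(p)
  B <- loop_field_kernel(loop$radius, loop$current,
                         pts[, 1] - loop$center[1],
                         pts[, 2] - loop$center[2],
                         pts[, 3] - loop$center[3])
  if (nrow(B) == 1) B[1, ] else B
}

#' Discretize a winding specification into loops
#'
#' Lays `turns` filamentary loops for a [winding_spec()]: turns fill each layer
#' vertically from `z = -height` upward at a pitch of one wire diameter; when a
#' layer is full the radius steps outward by one wire diameter. Layer `l`
#' (0-based) sits at radius `inner_radius + (l + 0.5) * wire_diameter`.
#'
#' @param spec a [winding_spec()].
#' @return a data frame of class `bm_winding` with one row per turn and columns
#'   `radius`, `z` (loop plane in the local frame) and `current`.
#' @examples
#' w <- build_winding(winding_spec(0.05, 0.04, 300, 0.9e-3, 10 / 3))
#' nrow(w)             # 300
#' length(unique(w$radius))  # 7 layers
#' @export
build_winding <- function(spec) {
  stopifnot(inherits(spec, "winding_spec"))
  per_layer <- floor(spec$height / spec$wire_diameter)
  idx <- seq_len(spec$turns) - 1L
  layer <- idx %/% per_layer
  pos <- idx %% per_layer
  out <- data.frame(
    radius = spec$inner_radius + (layer + 0.5) * spec$wire_diameter,
    z = -spec$height + (pos + 0.5) * spec$wire_diameter,
    current = spec$current
  )
  class(out) <- c("bm_winding", "data.frame")
  attr(out, "wire_diameter") <- spec$wire_diameter
  out
}

as_winding <- function(loops) {
  if (inherits(loops, "bm_winding")) return(loops)
  if (inherits(loops, "loop_source")) loops <- list(loops)
  if (is.list(loops) && all(vapply(loops, inherits, TRUE, "loop_source"))) {
    out <- data.frame(
      radius = vapply(loops, `[[`, 0, "radius"),
      z = vapply(loops, function(l) l$center[["z"]], 0),
      current = vapply(loops, `[[`, 0, "current")
    )
    if (any(vapply(loops, function(l) abs(l$center[["x"]]) + abs(l$center[["y"]]), 0) > 0))
      stop_config("coil_field expects coaxial loops; use array_field for displaced sources")
    class(out) <- c("bm_winding", "data.frame")
    return(out)
  }
  stop_config("loops must be a bm_winding data frame or a list of loop_source objects")
}

#' Field of a stack of coaxial loops
#'
#' Vector superposition of [loop_field()] over every turn of a winding.
#' Evaluation closer than `min_clearance` to any filament is refused rather
#' than returning a near-singular value.
#'
#' @param loops a `bm_winding` data frame from [build_winding()] or a list of
#'   coaxial [loop_source()] objects.
#' @param p evaluation point(s) in the winding's local frame (top face at z = 0).
#' @param min_clearance minimum allowed distance to any filament (m); defaults
#'   to the winding's wire diameter when known, else 0.
#' @return field vector(s) in tesla, as in [loop_field()]. An empty winding
#'   returns zeros.
#' @export
coil_field <- function(loops, p, min_clearance = NULL) {
  pts <- as_points(p)
  if ((is.data.frame(loops) || is.list(loops)) && length(loops) == 0 ||
      (is.data.frame(loops) && nrow(loops) == 0)) {
    B <- matrix(0, nrow(pts), 3, dimnames = list(NULL, c("bx", "by", "bz")))
    return(if (nrow(B) == 1) B[1, ] else B)
  }
  w <- as_winding(loops)
  if (is.null(min_clearance)) min_clearance <- attr(w, "wire_diameter") %||% 0
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  if (min_clearance > 0) {
    for (i in seq_len(nrow(w))) {
      d2 <- (rho - w$radius[i])^2 + (pts[, 3] - w$z[i])^2
      if (any(d2 < min_clearance^2))
        stop_domain(sprintf(
          "evaluation point within %g m of a winding filament (radius %g m, z = %g m)",
          min_clearance, w$radius[i], w$z[i]))
    }
  }
  B <- matrix(0, nrow(pts), 3, dimnames = list(NULL, c("bx", "by", "bz")))
  ## group identical (radius, z) turns so each unique filament costs one kernel call
  key <- paste(w$radius, w$z)
  for (k in split(seq_len(nrow(w)), key)) {
    B <- B + loop_field_kernel(w$radius[k[1]], sum(w$current[k]),
                               pts[, 1], pts[, 2], pts[, 3] - w$z[k[1]])
  }
  if (nrow(B) == 1) B[1, ] else B
}
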