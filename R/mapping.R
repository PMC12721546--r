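#' Map the flux density on a horizontal plane above the array
#'
#' Evaluates the array field on a rectangular grid at height `z_plane` above
#' the electromagnets' top faces and records the three components and the
#' magnitude at every node.
#'
#' @param array an [em_array()].
#' @param z_plane height of the plane in metres (> 0).
#' @param extent half-width specification: either a single full side length in
#'   metres (grid spans `[-extent/2, extent/2]` in x and y, default 0.16 m to
#'   cover a 16 cm container) or a length-4 vector `c(xmin, xmax, ymin, ymax)`.
#' @param n grid resolution per axis (>= 2; a scalar or `c(nx, ny)`).
#' @param model,method forwarded to [electromagnet_field()].
#' @return an object of class `field_map`: list with `z_plane`, `grid_x`,
#'   `grid_y`, component matrices `bx`, `by`, `bz`, `magnitude` (rows index x,
#'   columns y) and summary statistics `max`, `min`, `mean` of the magnitude.
#' @examples
#' \donttest{
#' em <- electromagnet(winding_spec(0.05, 0.04, 300, 0.9e-3, 10 / 3), core_spec(0.05, 0.04))
#' fm <- plane_field_map(triangular_array(em), 0.10, n = 21)
#' fm$max
#' }
#' @export
plane_field_map <- function(array, z_plane, extent = 0.16, n = 81,
                            model = "amplified", method = "concentrated") {
  stopifnot(inherits(array, "em_array"))
  check_num(z_plane, "z_plane", min = 0, strict_min = TRUE)
  if (length(n) == 1) n <- c(n, n)
  if (any(n < 2)) stop_config("grid resolution must be >= 2 per axis")
  if (length(extent) == 1) extent <- c(-extent / 2, extent / 2, -extent / 2, extent / 2)
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4])
    stop_config("extent must be a side length or c(xmin, xmax, ymin, ymax)")
  gx <- seq(extent[1], extent[2], length.out = n[1])
  gy <- seq(extent[3], extent[4], length.out = n[2])
  pts <- cbind(x = rep(gx, times = n[2]), y = rep(gy, each = n[1]), z = z_plane)
  B <- array_field(array, pts, model = model, method = method)
  mag <- sqrt(rowSums(B^2))
  shape <- function(v) matrix(v, n[1], n[2])
  structure(list(z_plane = z_plane, grid_x = gx, grid_y = gy,
                 bx = shape(B[, 1]), by = shape(B[, 2]), bz = shape(B[, 3]),
                 magnitude = shape(mag),
                 max = max(mag), min = min(mag), mean = mean(mag)),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> z = %g m, %d x %d grid over [%g, %g] x [%g, %g] m\n",
              x$z_plane, length(x$grid_x), length(x$grid_y),
              min(x$grid_x), max(x$grid_x), min(x$grid_y), max(x$grid_y)))
  cat(sprintf("  |B|: max %.4g T, min %.4g T, mean %.4g T\n", x$max, x$min, x$mean))
  invisible(x)
}

#' @export
as.data.frame.field_map <- function(x, ...) {
  data.frame(x_m = rep(x$grid_x, times = length(x$grid_y)),
             y_m = rep(x$grid_y, each = length(x$grid_x)),
             z_m = x$z_plane,
             bx_T = as.vector(x$bx), by_T = as.vector(x$by),
             bz_T = as.vector(x$bz), bmag_T = as.vector(x$magnitude))
}

#' Heat-map of a plane field map
#'
#' @param x a `field_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.field_map <- function(x, ...) {
  image(x$grid_x, x$grid_y, x$magnitude, col = hcl.colors(64, "viridis"),
        xlab = "x (m)", ylab = "y (m)", asp = 1,
        main = sprintf("|B| at z = %g m (max %.3g T)", x$z_plane, x$max), ...)
  contour(x$grid_x, x$grid_y, x$magnitude, add = TRUE, col = "white", lwd = 0.5)
  invisible(x)
}

#' Axial flux-density profile of a single electromagnet
#'
#' Samples `Bz` on the symmetry axis at `n_points` heights in `(0, z_max]`.
#' By symmetry the transverse components vanish on the axis and are not
#' stored. The `saturated` flag records whether the core amplification is
#' capped below `mu_r` (the regime drawn dashed in design charts).
#'
#' @param em an [electromagnet()].
#' @param z_max largest height (m, > 0).
#' @param n_points number of samples (default 50).
#' @param model,method forwarded to [electromagnet_field()].
#' @return an object of class `axis_profile`: list with `radius` (the coil
#'   inner radius, used as the curve label), `z`, `bz`, `saturated`, `turns`.
#' @export
axis_profile <- function(em, z_max, n_points = 50,
                         model = "amplified", method = "concentrated") {
  stopifnot(inherits(em, "electromagnet"))
  check_num(z_max, "z_max", min = 0, strict_min = TRUE)
  check_num(n_points, "n_points", min = 2)
  z <- seq(z_max / n_points, z_max, length.out = n_points)
  pts <- cbind(em$center[1], em$center[2], z)
  B <- electromagnet_field(em, pts, model = model, method = method)
  if (!is.matrix(B)) B <- matrix(B, 1, 3)
  structure(list(radius = em$winding$inner_radius, z = z, bz = B[, 3],
                 saturated = if (model == "amplified") is_saturated(em, method) else FALSE,
                 turns = em$winding$turns),
            class = "axis_profile")
}

#' @export
print.axis_profile <- function(x, ...) {
  cat(sprintf("<axis_profile> a = %g m, N = %d, %s; Bz(%.3g m) = %.4g T .. Bz(%.3g m) = %.4g T\n",
              x$radius, x$turns, if (x$saturated) "saturated" else "unsaturated",
              x$z[1], x$bz[1], x$z[length(x$z)], x$bz[length(x$bz)]))
  invisible(x)
}

#' @export
as.data.frame.axis_profile <- function(x, ...) {
  data.frame(z_m = x$z, bz_T = x$bz, saturated = x$saturated)
}

#' @export
plot.axis_profile <- function(x, ...) {
  plot(x$z, x$bz, type = "l", lty = if (x$saturated) 2 else 1,
       xlab = "z (m)", ylab = "Bz (T)",
       main = sprintf("a = %g m (%s)", x$radius,
                      if (x$saturated) "saturated" else "unsaturated"), ...)
  invisible(x)
}

#' Design sweep: axial profiles of candidate coil radii under a wire budget
#'
#' For each candidate radius the number of turns that a fixed wire mass
#' affords is `N = floor(L / (2 pi a1))`, where `L` is the wire length bought
#' by the budget (`wire_mass / linear_mass(gauge)`) and `a1` the first-layer
#' radius. The core and winding height scale with the candidate radius in the
#' proportions of `core_template`. One [axis_profile()] is produced per
#' radius, reproducing the classic "pick the radius" design chart: small radii
#' saturate and decay fast along z, large radii never saturate.
#'
#' @param radii candidate coil (core) radii in metres.
#' @param wire_mass_budget wire mass available per coil (kg).
#' @param gauge a [wire_gauge()] (e.g. `awg_gauge(20)`).
#' @param current coil current (A).
#' @param core_template a [core_spec()] whose radius:height proportion and
#'   magnetic properties are applied to every candidate.
#' @param z_max,n_points axis sampling, as in [axis_profile()].
#' @param wire_pitch effective winding pitch (m); default the gauge's bare
#'   diameter plus a 7 percent enamel allowance.
#' @return list of `axis_profile` objects (class `radius_sweep`), one per radius.
#' @examples
#' \donttest{
#' sw <- radius_sweep(c(0.05, 0.07), 0.33 * 0.45359237, awg_gauge(20), 10,
#'                    core_spec(0.05, 0.04), z_max = 0.1, n_points = 20)
#' sapply(sw, `[[`, "saturated")
#' }
#' @export
radius_sweep <- function(radii, wire_mass_budget, gauge, current, core_template,
                         z_max = 0.10, n_points = 50, wire_pitch = NULL) {
  check_num(radii, "radii", len = NA, min = 0, strict_min = TRUE)
  check_num(wire_mass_budget, "wire_mass_budget", min = 0, strict_min = TRUE)
  stopifnot(inherits(gauge, "wire_gauge"), inherits(core_template, "core_spec"))
  if (is.null(wire_pitch)) wire_pitch <- gauge$bare_diameter * 1.07
  wire_length <- wire_mass_budget / gauge$linear_mass
  profiles <- lapply(radii, function(a) {
    a1 <- a + 0.5 * wire_pitch
    turns <- floor(wire_length / (2 * pi * a1))
    if (turns < 1)
      stop_config("radius ", a, " m too large: the wire budget affords no full turn")
    height <- core_template$height * a / core_template$radius
    core <- core_spec(a, height, core_template$mu_r, core_template$b_sat)
    em <- electromagnet(winding_spec(a, height, turns, wire_pitch, current), core)
    axis_profile(em, z_max, n_points)
  })
  class(profiles) <- c("radius_sweep", "list")
  profiles
}

#' @export
print.radius_sweep <- function(x, ...) {
  cat(sprintf("<radius_sweep> %d candidate radii\n", length(x)))
  for (p in x)
    cat(sprintf("  a = %4.3g m: N = %3d, %s\n", p$radius, p$turns,
                if (p$saturated) "saturated" else "unsaturated"))
  invisible(x)
}

#' @export
plot.radius_sweep <- function(x, ...) {
  zr <- range(unlist(lapply(x, `[[`, "z")))
  br <- range(unlist(lapply(x, `[[`, "bz")))
  plot(NA, xlim = zr, ylim = br, xlab = "z (m)", ylab = "Bz (T)",
       main = "Axial profiles (dashed = core saturated)", ...)
  for (i in seq_along(x))
    lines(x[[i]]$z, x[[i]]$bz, col = i, lty = if (x[[i]]$saturated) 2 else 1)
  legend("topright", legend = sprintf("a = %g m", vapply(x, `[[`, 0, "radius")),
         col = seq_along(x), lty = 1, cex = 0.8)
  invisible(x)
}
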