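#' Cartesian point
#'
#' Positions are expressed in metres with `z = 0` at the plane of the
#' electromagnets' top faces and +z pointing into the container interior.
#'
#' @param x,y,z coordinates in metres.
#' @return a named numeric vector of class `point3`.
#' @examples
#' point3(0, 0, 0.10)  # 10 cm above the array surface
#' @export
point3 <- function(x = 0, y = 0, z = 0) {
  p <- c(x = unname(check_num(x, "x")), y = unname(check_num(y, "y")),
         z = unname(check_num(z, "z")))
  class(p) <- "point3"
  p
}

as_points <- function(p) {
  ## Accept a point3, a length-3 numeric, or an n x 3 matrix / data.frame.
  if (inherits(p, "point3") || (is.numeric(p) && is.null(dim(p)) && length(p) == 3))
    return(matrix(as.numeric(p), nrow = 1, dimnames = list(NULL, c("x", "y", "z"))))
  p <- as.matrix(p)
  if (ncol(p) != 3) stop_config("points must have 3 columns (x, y, z)")
  colnames(p) <- c("x", "y", "z")
  storage.mode(p) <- "double"
  p
}

#' Single circular current loop
#'
#' The elementary source of the magnetostatic model: a filamentary circular
#' loop of radius `radius` carrying current `current`, with its axis parallel
#' to +z.
#'
#' @param radius loop radius in metres (> 0).
#' @param current signed current in amperes.
#' @param center loop centre, a [point3()] (default origin).
#' @return an object of class `loop_source`.
#' @examples
#' loop_source(0.05, 10)
#' @export
loop_source <- function(radius, current, center = point3()) {
  check_num(radius, "radius", min = 0, strict_min = TRUE)
  check_num(current, "current")
  structure(list(radius = radius, current = current, center = point3(center[1], center[2], center[3])),
            class = "loop_source")
}

#' Winding specification
#'
#' Describes a layered solenoid winding. Turns are laid at a vertical pitch
#' equal to `wire_diameter` (the effective enamelled diameter); when a layer
#' is full the radius grows by one wire diameter. The winding occupies
#' `z` in `[-height, 0]` of its electromagnet's local frame.
#'
#' @param inner_radius innermost layer sits at `inner_radius + wire_diameter/2` (m).
#' @param height axial length of the winding (m).
#' @param turns total number of turns (integer >= 1).
#' @param wire_diameter effective wire pitch, bare diameter plus insulation (m).
#' @param current current per coil in amperes.
#' @return an object of class `winding_spec`.
#' @examples
#' winding_spec(0.05, 0.04, 300, 0.9e-3, 10 / 3)
#' @export
winding_spec <- function(inner_radius, height, turns, wire_diameter, current) {
  check_num(inner_radius, "inner_radius", min = 0, strict_min = TRUE)
  check_num(height, "height", min = 0, strict_min = TRUE)
  check_num(turns, "turns", min = 1)
  if (turns != round(turns)) stop_config("turns must be an integer")
  check_num(wire_diameter, "wire_diameter", min = 0, strict_min = TRUE)
  if (wire_diameter >= height)
    stop_config("wire_diameter (", wire_diameter, " m) must be smaller than the winding height (",
                height, " m): no turn fits")
  check_num(current, "current")
  structure(list(inner_radius = inner_radius, height = height, turns = as.integer(turns),
                 wire_diameter = wire_diameter, current = current),
            class = "winding_spec")
}

#' Ferromagnetic core specification
#'
#' A cylindrical low-carbon steel core characterised by its relative
#' permeability `mu_r` and saturation flux density `b_sat`. The reference
#' material is ASTM A36 structural steel with an assumed `mu_r` of 200 and a
#' saturation point of 2.16 T.
#'
#' @param radius core radius (m).
#' @param height core height (m).
#' @param mu_r relative permeability (>= 1, dimensionless).
#' @param b_sat saturation flux density (T, > 0).
#' @return an object of class `core_spec`.
#' @examples
#' core_spec(0.05, 0.04, 200, 2.16)
#' @export
core_spec <- function(radius, height, mu_r = 200, b_sat = 2.16) {
  check_num(radius, "radius", min = 0, strict_min = TRUE)
  check_num(height, "height", min = 0, strict_min = TRUE)
  check_num(mu_r, "mu_r", min = 1)
  check_num(b_sat, "b_sat", min = 0, strict_min = TRUE)
  structure(list(radius = radius, height = height, mu_r = mu_r, b_sat = b_sat,
                 volume = pi * radius^2 * height),
            class = "core_spec")
}

#' Electromagnet: winding + saturable core + placement
#'
#' The winding and core share a vertical axis through `center`; the top faces
#' sit at `z = 0` of the local frame (the device convention places all
#' electromagnet top faces in the global `z = 0` plane).
#'
#' @param winding a [winding_spec()].
#' @param core a [core_spec()]; its radius must not exceed the winding inner radius.
#' @param center a [point3()] giving the axis position; the `z` component is the
#'   global height of the top face (0 by convention).
#' @return an object of class `electromagnet`.
#' @examples
#' em <- electromagnet(winding_spec(0.05, 0.04, 300, 0.9e-3, 10 / 3),
#'                     core_spec(0.05, 0.04))
#' @export
electromagnet <- function(winding, core, center = point3()) {
  stopifnot(inherits(winding, "winding_spec"), inherits(core, "core_spec"))
  if (core$radius > winding$inner_radius + 1e-12)
    stop_config("core radius (", core$radius, " m) exceeds winding inner_radius (",
                winding$inner_radius, " m)")
  structure(list(winding = winding, core = core,
                 center = point3(center[1], center[2], center[3])),
            class = "electromagnet")
}

#' Planar array of electromagnets
#'
#' @param ... one or more [electromagnet()] objects (or a single list of them).
#' @return an object of class `em_array`.
#' @seealso [triangular_array()] for the standard three-coil layout.
#' @export
em_array <- function(...) {
  ems <- list(...)
  if (length(ems) == 1 && !inherits(ems[[1]], "electromagnet")) ems <- ems[[1]]
  if (length(ems) == 0) stop_config("em_array needs at least one electromagnet")
  if (!all(vapply(ems, inherits, TRUE, "electromagnet")))
    stop_config("all elements must be electromagnet objects")
  z <- vapply(ems, function(e) e$center["z"], 0)
  if (diff(range(z)) > 1e-12)
    stop_config("all electromagnet top faces must be coplanar at z = 0")
  structure(list(electromagnets = ems), class = "em_array")
}

#' Triangular three-electromagnet array
#'
#' Places three copies of `em` with vertical axes on a circle about the
#' container axis. The default circle radius `2/sqrt(3)` times the coil outer
#' radius makes neighbouring coils mutually tangent, the tightest triangular
#' packing under the container.
#'
#' @param em template [electromagnet()].
#' @param circumradius distance of each coil axis from the array centroid (m);
#'   default mutually tangent spacing.
#' @return an [em_array()] of three electromagnets.
#' @examples
#' em <- electromagnet(winding_spec(0.05, 0.04, 300, 0.9e-3, 10 / 3), core_spec(0.05, 0.04))
#' arr <- triangular_array(em)
#' @export
triangular_array <- function(em, circumradius = NULL) {
  stopifnot(inherits(em, "electromagnet"))
  if (is.null(circumradius))
    circumradius <- 2 / sqrt(3) * em$winding$inner_radius
  check_num(circumradius, "circumradius", min = 0)
  ang <- c(90, 210, 330) * pi / 180
  ems <- lapply(ang, function(a)
    electromagnet(em$winding, em$core,
                  point3(circumradius * cos(a), circumradius * sin(a), 0)))
  em_array(ems)
}

#' @export
print.loop_source <- function(x, ...) {
  cat(sprintf("<loop_source> a = %g m, I = %g A, centre (%g, %g, %g) m\n",
              x$radius, x$current, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' @export
print.winding_spec <- function(x, ...) {
  per_layer <- floor(x$height / x$wire_diameter)
  cat(sprintf("<winding_spec> %d turns, inner radius %g m, height %g m\n",
              x$turns, x$inner_radius, x$height))
  cat(sprintf("  pitch %g mm -> %d turns/layer, %d layer(s); %g A per coil\n",
              x$wire_diameter * 1e3, per_layer, ceiling(x$turns / per_layer), x$current))
  invisible(x)
}

#' @export
print.core_spec <- function(x, ...) {
  cat(sprintf("<core_spec> radius %g m, height %g m, mu_r = %g, Bsat = %g T (V = %.4g m^3)\n",
              x$radius, x$height, x$mu_r, x$b_sat, x$volume))
  invisible(x)
}

#' @export
print.electromagnet <- function(x, ...) {
  cat("<electromagnet>\n")
  print(x$winding)
  print(x$core)
  cat(sprintf("  centre (%g, %g, %g) m; amplification gain %.4g (%s)\n",
              x$center[1], x$center[2], x$center[3], core_amplification(x),
              if (is_saturated(x)) "saturated" else "unsaturated"))
  invisible(x)
}

#' @export
print.em_array <- function(x, ...) {
  cat(sprintf("<em_array> %d electromagnet(s)\n", length(x$electromagnets)))
  for (e in x$electromagnets)
    cat(sprintf("  a = %g m, N = %d, I = %g A at (%.4g, %.4g) m\n",
                e$winding$inner_radius, e$winding$turns, e$winding$current,
                e$center[1], e$center[2]))
  invisible(x)
}
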