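# Reduced-order hydrodynamic closures for a sphere in tube flow: laminar
# velocity profile, Schiller-Naumann drag with a near-wall correction,
# shear-induced (Saffman-type) lift with a wall-decay factor, and the net
# buoyant weight. These closures stand in for resolved CFD of the moving
# bead; see the methods vignette for their validity envelope.

#' Tube flow configuration
#'
#' @param tube_radius Inner tube radius (m), > 0.
#' @param mean_velocity Cross-section mean velocity (m/s), >= 0.
#' @param viscosity Dynamic viscosity (Pa s), > 0.
#' @param fluid_density Fluid density (kg/m^3), > 0.
#' @param profile `"laminar"` (parabolic) or `"plug"` (uniform).
#' @return An object of class `flow_config`.
#' @examples
#' flow_config()  # water at 0.32 m/s in an 8 mm tube
#' @export
flow_config <- function(tube_radius = 0.004, mean_velocity = 0.32,
                        viscosity = 0.00102, fluid_density = 1000,
                        profile = c("laminar", "plug")) {
  check_number(tube_radius, "tube_radius", positive = TRUE)
  check_number(mean_velocity, "mean_velocity", nonnegative = TRUE)
  check_number(viscosity, "viscosity", positive = TRUE)
  check_number(fluid_density, "fluid_density", positive = TRUE)
  profile <- match.arg(profile)
  structure(list(tube_radius = tube_radius, mean_velocity = mean_velocity,
                 viscosity = viscosity, fluid_density = fluid_density,
                 profile = profile),
            class = "flow_config")
}

#' Axial fluid velocity at a radial position
#'
#' Laminar (Poiseuille) profile \eqn{u(r) = 2 U (1 - r^2/R^2)}, zero at the
#' wall and twice the mean on the axis; the plug profile returns the mean
#' velocity everywhere.
#'
#' @param r Radial position (m), |r| <= tube radius; vectorized.
#' @param flow A [flow_config()].
#' @return Axial velocity (m/s).
#' @examples
#' poiseuille_velocity(0, flow_config())  # 0.64 m/s centerline
#' @export
poiseuille_velocity <- function(r, flow) {
  stopifnot(inherits(flow, "flow_config"))
  if (any(!is.finite(r)) || any(abs(r) > flow$tube_radius))
    stop_domain("'r' must satisfy |r| <= tube_radius")
  if (flow$profile == "plug") return(rep(flow$mean_velocity, length(r)))
  2 * flow$mean_velocity * (1 - r^2 / flow$tube_radius^2)
}

#' Local shear rate of the undisturbed profile
#'
#' Magnitude of du/dr at radial position `r`: \eqn{4 U |r| / R^2} for the
#' laminar profile, zero for plug flow.
#'
#' @inheritParams poiseuille_velocity
#' @return Shear rate (1/s), >= 0.
#' @export
local_shear_rate <- function(r, flow) {
  stopifnot(inherits(flow, "flow_config"))
  if (any(!is.finite(r)) || any(abs(r) > flow$tube_radius))
    stop_domain("'r' must satisfy |r| <= tube_radius")
  if (flow$profile == "plug") return(rep(0, length(r)))
  4 * flow$mean_velocity * abs(r) / flow$tube_radius^2
}

#' Near-wall drag correction factor
#'
#' Faxen-type enhancement of the drag on a sphere translating parallel to a
#' plane wall, parameterized by the ratio of bead radius to center-wall
#' distance and capped at 3 so the closure stays bounded and continuous at
#' contact.
#'
#' @param wall_gap Distance from the bead surface to the wall (m), >= 0;
#'   `Inf` for unbounded flow.
#' @param bead_diameter Bead diameter (m).
#' @return Multiplicative drag factor >= 1.
#' @export
wall_drag_factor <- function(wall_gap, bead_diameter) {
  check_number(bead_diameter, "bead_diameter", positive = TRUE)
  check_number(wall_gap, "wall_gap", nonnegative = TRUE, finite = FALSE)
  a <- bead_diameter / 2
  xi <- a / (a + wall_gap)
  min(3, 1 / (1 - 9 / 16 * xi + xi^3 / 8))
}

#' Hydrodynamic drag on the bead
#'
#' Schiller-Naumann correlation
#' \eqn{C_D = (24/Re)(1 + 0.15 Re^{0.687})} applied to the slip velocity,
#' multiplied by the near-wall factor of [wall_drag_factor()]. Reduces to
#' Stokes drag \eqn{3\pi\mu d V} as \eqn{Re \to 0}. The returned force is
#' signed with `rel_velocity` (the fluid-minus-bead slip), i.e. it drives
#' the bead toward the local fluid velocity. Slip Reynolds numbers beyond
#' 800 are outside the correlation's validated range and trigger a warning.
#'
#' @param rel_velocity Slip velocity, fluid minus bead (m/s); signed.
#' @param bead_diameter Bead diameter (m).
#' @param flow A [flow_config()].
#' @param wall_gap Bead-surface-to-wall distance (m); default `Inf`.
#' @param calibration Multiplicative calibration constant; default 1 (bare
#'   correlation). The trajectory simulator applies its single documented
#'   drag-calibration constant through this argument.
#' @return Signed drag force (N).
#' @examples
#' drag_force(1e-4, 0.00238, flow_config())  # Stokes regime, ~2.3e-9 N
#' @export
drag_force <- function(rel_velocity, bead_diameter, flow, wall_gap = Inf,
                       calibration = 1) {
  stopifnot(inherits(flow, "flow_config"))
  check_number(rel_velocity, "rel_velocity")
  check_number(bead_diameter, "bead_diameter", positive = TRUE)
  check_number(calibration, "calibration", positive = TRUE)
  v <- abs(rel_velocity)
  if (v == 0) return(0)
  re <- flow$fluid_density * v * bead_diameter / flow$viscosity
  if (re > 800)
    warning(sprintf("slip Reynolds number %.0f exceeds the validated range (800) of the drag correlation", re))
  cd <- 24 / re * (1 + 0.15 * re^0.687)
  area <- pi / 4 * bead_diameter^2
  f <- calibration * wall_drag_factor(wall_gap, bead_diameter) *
    cd * 0.5 * flow$fluid_density * v^2 * area
  sign(rel_velocity) * f
}

#' Shear-induced lift on the bead
#'
#' Saffman-form magnitude \eqn{C_L \mu d^2 |V_{rel}| \sqrt{S/\nu}}
#' multiplied by a wall-decay factor \eqn{(d/(d + gap))^2}: strongest for a
#' bead at the wall, decaying smoothly as the gap opens (the wall-induced
#' pressure asymmetry that generates the lift weakens with distance). The
#' default coefficient \eqn{C_L = 2.6} exceeds Saffman's analytic
#' small-Reynolds value 1.615 because at the bead's slip Reynolds numbers
#' (order 100 to 1000) the wall-induced inertial lift is stronger than the
#' unbounded-shear asymptote; it is set so the reference bead travels
#' suspended in the stream rather than rolling along the wall, as observed.
#' The closure vanishes when either the shear rate or the slip velocity is
#' zero. The returned value is a magnitude; the caller orients it away from
#' the nearest wall.
#'
#' @param shear_rate Local shear rate of the undisturbed flow (1/s), >= 0.
#' @param rel_velocity Slip speed (m/s), >= 0.
#' @param bead_diameter Bead diameter (m).
#' @param flow A [flow_config()].
#' @param wall_gap Bead-surface-to-wall distance (m), >= 0.
#' @param coefficient Lift coefficient \eqn{C_L}; default 2.6.
#' @return Lift force magnitude (N), directed away from the wall.
#' @export
lift_force <- function(shear_rate, rel_velocity, bead_diameter, flow,
                       wall_gap = 0, coefficient = 2.6) {
  stopifnot(inherits(flow, "flow_config"))
  check_number(shear_rate, "shear_rate", nonnegative = TRUE)
  check_number(rel_velocity, "rel_velocity", nonnegative = TRUE)
  check_number(bead_diameter, "bead_diameter", positive = TRUE)
  check_number(wall_gap, "wall_gap", nonnegative = TRUE, finite = FALSE)
  check_number(coefficient, "coefficient", positive = TRUE)
  if (shear_rate == 0 || rel_velocity == 0) return(0)
  nu <- flow$viscosity / flow$fluid_density
  decay <- (bead_diameter / (bead_diameter + wall_gap))^2
  coefficient * flow$viscosity * bead_diameter^2 * rel_velocity *
    sqrt(shear_rate / nu) * decay
}

#' Net buoyant weight of the bead
#'
#' \eqn{(\rho_{bead} - \rho_{fluid}) V g}, positive downward when the bead
#' is denser than the fluid.
#'
#' @param bead_diameter Bead diameter (m).
#' @param bead_density Bead density (kg/m^3).
#' @param flow A [flow_config()] (supplies the fluid density).
#' @param g Gravitational acceleration (m/s^2); default 9.8.
#' @return Net downward force (N); negative for a buoyant bead.
#' @examples
#' gravity_buoyancy(0.00238, 1110, flow_config())  # ~7.6e-6 N
#' @export
gravity_buoyancy <- function(bead_diameter, bead_density, flow, g = 9.8) {
  stopifnot(inherits(flow, "flow_config"))
  check_number(bead_diameter, "bead_diameter", positive = TRUE)
  check_number(bead_density, "bead_density", positive = TRUE)
  check_number(g, "g", positive = TRUE)
  (bead_density - flow$fluid_density) * pi / 6 * bead_diameter^3 * g
}

#' Terminal settling velocity in quiescent fluid
#'
#' Speed at which the drag closure balances the net buoyant weight, found by
#' root bracketing on the force balance (far from walls, bare correlation).
#'
#' @inheritParams gravity_buoyancy
#' @return Terminal speed (m/s); 0 for a neutrally buoyant bead.
#' @examples
#' terminal_velocity(0.00238, 1110, flow_config())  # ~0.060 m/s
#' @export
terminal_velocity <- function(bead_diameter, bead_density, flow, g = 9.8) {
  w <- abs(gravity_buoyancy(bead_diameter, bead_density, flow, g = g))
  if (w == 0) return(0)
  f <- function(v) {
    suppressWarnings(drag_force(v, bead_diameter, flow)) - w
  }
  stats::uniroot(f, lower = 1e-9, upper = 100, tol = 1e-12)$root
}
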