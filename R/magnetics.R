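# Electromagnet field model, single-bead magnetostatic attraction force,
# dipole-dipole array corrections, and parametric magnetization loops.
#
# Field strengths are in A/m unless an argument is explicitly marked kA/m
# (loop parameters and force-curve grids follow the measurement convention
# and use kA/m).

#' Electromagnet model
#'
#' Axial field law \eqn{H(z) = H_0 (1 - c z)} (clamped at zero), with the
#' decay coefficient `c` expressed per millimetre of distance from the core
#' surface, plus the core footprint geometry needed for trajectory runs.
#'
#' @param h0 Field strength at the core surface (A/m), >= 0. The calibrated
#'   range of the reference electromagnet is 0 to 43 kA/m.
#' @param decay_coeff Linear decay coefficient (1/mm); default 0.073.
#' @param core_diameter Core diameter (m); default 0.018.
#' @param gap Distance from the core surface to the bead container wall (m);
#'   4 mm in the force-measurement setup, 1.5 mm (the tube wall) in the flow
#'   setup.
#' @param center_x Axial position of the core center along the tube (m);
#'   used by the trajectory simulator.
#' @return An object of class `magnet_model`.
#' @examples
#' magnet_model(h0 = 40e3)
#' @export
magnet_model <- function(h0, decay_coeff = 0.073, core_diameter = 0.018,
                         gap = 0.004, center_x = 0) {
  check_number(h0, "h0", nonnegative = TRUE)
  check_number(decay_coeff, "decay_coeff", positive = TRUE)
  check_number(core_diameter, "core_diameter", positive = TRUE)
  check_number(gap, "gap", nonnegative = TRUE)
  check_number(center_x, "center_x")
  structure(list(h0 = h0, decay_coeff = decay_coeff,
                 core_diameter = core_diameter, gap = gap,
                 center_x = center_x),
            class = "magnet_model")
}

#' Axial field strength at a distance from the core surface
#'
#' \eqn{H(z) = \max(0, H_0 (1 - c z))} with `z` in millimetres.
#'
#' @param z Distance from the core surface (mm), >= 0; vectorized.
#' @param magnet A [magnet_model()].
#' @return Field strength (A/m), same units as `magnet$h0`.
#' @examples
#' m <- magnet_model(h0 = 43e3)
#' field_at(c(0, 4), m)
#' @export
field_at <- function(z, magnet) {
  stopifnot(inherits(magnet, "magnet_model"))
  if (any(!is.finite(z)) || any(z < 0))
    stop_domain("'z' must be finite and >= 0 (distance from the core surface, mm)")
  pmax(0, magnet$h0 * (1 - magnet$decay_coeff * z))
}

#' Lateral roll-off of the field along the tube axis
#'
#' The axial decay law holds over the core footprint; away from the core
#' center the field falls off. The roll-off is modelled as a Gaussian weight
#' \eqn{w(x) = \exp(-x^2 / 2\sigma^2)} with \eqn{\sigma} set so that the
#' weight is 0.05 at 1.5 core radii — smooth, even, monotone in |x| and
#' negligible beyond the footprint.
#'
#' @param x Axial offset from the core center (m); vectorized.
#' @param magnet A [magnet_model()].
#' @return Dimensionless weight in \[0, 1\].
#' @export
lateral_field_profile <- function(x, magnet) {
  stopifnot(inherits(magnet, "magnet_model"))
  sigma <- 0.75 * magnet$core_diameter / sqrt(2 * log(20))
  exp(-x^2 / (2 * sigma^2))
}

#' Bead magnetic description
#'
#' @param diameter Bead diameter (m), > 0.
#' @param chi Volume magnetic susceptibility (SI, dimensionless), >= 0.
#' @param demag_factor Demagnetization factor in \[0, 1\]; 1/3 for a sphere.
#' @return An object of class `bead_magnetics` (also carries the bead volume
#'   `volume` and the demagnetization-corrected `chi_eff`).
#' @examples
#' bead_magnetics(diameter = 0.00238, chi = 0.13)
#' @export
bead_magnetics <- function(diameter, chi, demag_factor = 1 / 3) {
  check_number(diameter, "diameter", positive = TRUE)
  check_number(chi, "chi", nonnegative = TRUE)
  check_fraction(demag_factor, "demag_factor")
  structure(list(diameter = diameter, chi = chi, demag_factor = demag_factor,
                 volume = pi / 6 * diameter^3,
                 chi_eff = chi / (1 + demag_factor * chi)),
            class = "bead_magnetics")
}

#' Magnetostatic attraction force on a single bead
#'
#' Gradient-field force on a linearly magnetizable sphere between two face
#' fields: \eqn{F = \mu_0 \chi_{eff} (V/d) (H_2^2 - H_1^2)/2} with
#' \eqn{\chi_{eff} = \chi / (1 + N\chi)}. For the linear axial field law the
#' expression equals the volume average of \eqn{\mu_0 \chi_{eff} H \,dH/dz}
#' over the sphere. Positive values point toward the magnet (from face 1
#' toward face 2); if `h1 > h2` the signed value flips.
#'
#' @param bead A [bead_magnetics()].
#' @param h1 Field at the bead face remote from the magnet (A/m).
#' @param h2 Field at the bead face near the magnet (A/m).
#' @return Signed force (N).
#' @examples
#' b <- bead_magnetics(0.00238, chi = 0.13)
#' m <- magnet_model(h0 = 37.4e3)
#' h2 <- field_at(4, m); h1 <- field_at(4 + 2.38, m)
#' single_bead_force(b, h1, h2)
#' @export
single_bead_force <- function(bead, h1, h2) {
  stopifnot(inherits(bead, "bead_magnetics"))
  check_number(h1, "h1", nonnegative = TRUE)
  check_number(h2, "h2", nonnegative = TRUE)
  MU0 * bead$chi_eff * (bead$volume / bead$diameter) * (h2^2 - h1^2) / 2
}

#' Attraction force of a bead sitting at the container wall
#'
#' Convenience wrapper computing the face fields from the magnet geometry:
#' the near face is at the gap distance, the remote face one bead diameter
#' further.
#'
#' @inheritParams single_bead_force
#' @param magnet A [magnet_model()].
#' @return Force toward the magnet (N).
#' @export
bead_attraction_force <- function(bead, magnet) {
  stopifnot(inherits(bead, "bead_magnetics"), inherits(magnet, "magnet_model"))
  gap_mm <- magnet$gap * 1000
  d_mm <- bead$diameter * 1000
  single_bead_force(bead,
                    h1 = field_at(gap_mm + d_mm, magnet),
                    h2 = field_at(gap_mm, magnet))
}

#' Additional field at a bead from a magnetized neighbor
#'
#' Axial dipole field of a neighboring bead of moment `m` at center-to-center
#' distance `spacing` along the chain axis: \eqn{H^* = 2m/(4\pi s^3)} for a
#' first-type (adjacent chain) neighbor; a second-type neighbor contributes
#' exactly one eighth of that.
#'
#' @param moment Bead magnetic moment (A m^2), >= 0.
#' @param spacing Center-to-center lattice spacing (m), > 0.
#' @param neighbor_class 1 (adjacent chain neighbor) or 2 (next shell).
#' @return Additional field strength (A/m).
#' @examples
#' dipole_correction_field(1, 0.1, 1)  # 2 / (4 pi 1e-3) = 159.15
#' @export
dipole_correction_field <- function(moment, spacing, neighbor_class = 1) {
  check_number(moment, "moment", nonnegative = TRUE)
  check_number(spacing, "spacing", positive = TRUE)
  if (!neighbor_class %in% c(1, 2))
    stop_domain("'neighbor_class' must be 1 or 2")
  h <- 2 * moment / (4 * pi * spacing^3)
  if (neighbor_class == 2) h <- h / 8
  h
}

#' Array geometry for dipole-dipole corrections
#'
#' Default geometry is a field-projected chain: two first-type neighbors at
#' the lattice spacing and two second-type neighbors contributing one eighth
#' of the first-type field each. Hexagonal in-plane counts (6 and 6) can be
#' requested for densely packed monolayers.
#'
#' @param lattice_spacing Center-to-center distance between beads (m).
#' @param n_first,n_second Numbers of first- and second-type neighbors.
#' @param correction_level One of `"none"`, `"first"`, `"first_plus_curve"`,
#'   `"first_and_second"`.
#' @return An object of class `array_geometry`.
#' @export
array_geometry <- function(lattice_spacing, n_first = 2, n_second = 2,
                           correction_level = c("none", "first",
                                                "first_plus_curve",
                                                "first_and_second")) {
  check_number(lattice_spacing, "lattice_spacing", positive = TRUE)
  check_number(n_first, "n_first", nonnegative = TRUE)
  check_number(n_second, "n_second", nonnegative = TRUE)
  correction_level <- match.arg(correction_level)
  structure(list(lattice_spacing = lattice_spacing, n_first = n_first,
                 n_second = n_second, correction_level = correction_level),
            class = "array_geometry")
}

# Self-consistent field-enhancement solve at one applied field (A/m).
# The bead moment magnetizes its neighbors, whose dipole fields add to the
# effective field; damped fixed-point iteration on the moment.
solve_effective_field <- function(h_applied, bead, geom, chi_eff_fun,
                                  tol = 1e-9, max_iter = 100, damping = 0.5) {
  if (h_applied <= 0) return(list(h_eff = 0, moment = 0, iterations = 0L))
  s <- geom$lattice_spacing
  n1 <- if (geom$correction_level %in% c("first", "first_plus_curve",
                                         "first_and_second")) geom$n_first else 0
  n2 <- if (geom$correction_level == "first_and_second") geom$n_second else 0
  coupling <- (n1 + n2 / 8) * 2 / (4 * pi * s^3)
  m <- chi_eff_fun(h_applied) * bead$volume * h_applied
  for (iter in seq_len(max_iter)) {
    h_eff <- h_applied + coupling * m
    m_new <- chi_eff_fun(h_eff) * bead$volume * h_eff
    if (abs(m_new - m) <= tol * max(abs(m_new), 1e-300)) {
      return(list(h_eff = h_applied + coupling * m_new, moment = m_new,
                  iterations = iter))
    }
    m <- (1 - damping) * m + damping * m_new
  }
  stop_domain(sprintf(
    "self-consistent moment iteration did not converge in %d iterations (last relative change %.3g at H = %g A/m)",
    max_iter, abs(m_new - m) / max(abs(m_new), 1e-300), h_applied))
}

#' Per-bead force curve with dipole-dipole array corrections
#'
#' Computes the attraction force per bead over a grid of surface field
#' strengths, optionally correcting the effective field for the induced
#' moments of neighboring beads. The neighbor moments are solved
#' self-consistently (damped fixed point, relative tolerance 1e-9, at most
#' 100 iterations). At `correction_level = "none"` the curve reproduces
#' [single_bead_force()] pointwise; higher correction levels dominate lower
#' ones pointwise.
#'
#' `correction_level = "first_plus_curve"` additionally replaces the constant
#' susceptibility by the field-dependent anhysteretic value
#' \eqn{\chi(H) = \phi M(H)/H} taken from the filler magnetization loop
#' scaled by the filler volume fraction; `material` and `phi` are then
#' required.
#'
#' @param bead A [bead_magnetics()].
#' @param magnet A [magnet_model()]; `h0` is overridden by the grid.
#' @param geom An [array_geometry()].
#' @param h0_grid Surface field strengths (kA/m), nonnegative and sorted.
#' @param material A [magnetic_material()], needed for
#'   `"first_plus_curve"`.
#' @param phi Filler volume fraction in the bead, needed for
#'   `"first_plus_curve"`.
#' @return A data frame of class `force_curve` with columns `h0_kA_m` and
#'   `force_N`, and attribute `correction_level`.
#' @examples
#' b <- bead_magnetics(0.00238, chi = 0.13)
#' m <- magnet_model(h0 = 0)
#' g <- array_geometry(0.00238, correction_level = "first")
#' array_force_curve(b, m, g, h0_grid = seq(0, 43, by = 43 / 8))
#' @export
array_force_curve <- function(bead, magnet, geom, h0_grid,
                              material = NULL, phi = NULL) {
  stopifnot(inherits(bead, "bead_magnetics"),
            inherits(magnet, "magnet_model"),
            inherits(geom, "array_geometry"))
  if (any(!is.finite(h0_grid)) || any(h0_grid < 0))
    stop_domain("'h0_grid' must be finite and nonnegative (kA/m)")
  if (is.unsorted(h0_grid))
    stop_domain("'h0_grid' must be sorted increasing")

  if (geom$correction_level == "first_plus_curve") {
    if (is.null(material) || is.null(phi))
      stop_domain("'first_plus_curve' needs 'material' and 'phi'")
    check_fraction(phi, "phi")
    chi_fun <- function(h_si) {
      h_ka <- h_si / 1000
      chi <- if (h_ka < 1e-9) {
        phi * material$ms / material$shape_field
      } else {
        phi * material$ms * tanh(h_ka / material$shape_field) / h_ka
      }
      chi / (1 + bead$demag_factor * chi)
    }
  } else {
    chi_fun <- function(h_si) bead$chi_eff
  }

  gap_mm <- magnet$gap * 1000
  d_mm <- bead$diameter * 1000
  zc_mm <- gap_mm + d_mm / 2

  force <- vapply(h0_grid, function(h0_ka) {
    mag <- magnet_model(h0 = h0_ka * 1000, decay_coeff = magnet$decay_coeff,
                        core_diameter = magnet$core_diameter,
                        gap = magnet$gap, center_x = magnet$center_x)
    h_center <- field_at(zc_mm, mag)
    sol <- solve_effective_field(h_center, bead, geom, chi_fun)
    beta <- if (h_center > 0) sol$h_eff / h_center else 1
    h2 <- field_at(gap_mm, mag) * beta
    h1 <- field_at(gap_mm + d_mm, mag) * beta
    chi_eff <- chi_fun(sol$h_eff)
    MU0 * chi_eff * (bead$volume / bead$diameter) * (h2^2 - h1^2) / 2
  }, numeric(1))

  out <- data.frame(h0_kA_m = h0_grid, force_N = force)
  attr(out, "correction_level") <- geom$correction_level
  class(out) <- c("force_curve", class(out))
  out
}

#' Magnetic material parameters for parametric hysteresis loops
#'
#' Parameterizes a two-branch hyperbolic-tangent hysteresis loop by its
#' saturation magnetization, remanence and coercivity. The loop shape field
#' \eqn{H_s} defaults to \eqn{H_c / \mathrm{artanh}(M_r/M_s)}, which makes
#' each branch pass through both the coercive field and the remanence point.
#'
#' @param ms Saturation magnetization (kA/m), > 0.
#' @param mr Remnant magnetization (kA/m), in \[0, `ms`).
#' @param hc Coercivity (kA/m), >= 0. Must be 0 when `mr = 0`
#'   (anhysteretic material) and > 0 when `mr > 0`.
#' @param shape_field Loop shape field \eqn{H_s} (kA/m); required when
#'   `mr = 0`, derived otherwise.
#' @return An object of class `magnetic_material`.
#' @examples
#' magnetic_material(ms = 388, mr = 30, hc = 6.2)  # shape field ~80 kA/m
#' @export
magnetic_material <- function(ms, mr, hc, shape_field = NULL) {
  check_number(ms, "ms", positive = TRUE)
  check_number(mr, "mr", nonnegative = TRUE)
  check_number(hc, "hc", nonnegative = TRUE)
  if (mr >= ms)
    stop_domain("'mr' must be < 'ms'")
  if (mr > 0 && hc <= 0)
    stop_domain("a material with remanence must have positive coercivity")
  if (mr == 0 && hc > 0)
    stop_domain("an anhysteretic material ('mr' = 0) must have 'hc' = 0")
  if (is.null(shape_field)) {
    if (mr == 0)
      stop_domain("'shape_field' is required when 'mr' = 0")
    shape_field <- hc / atanh(mr / ms)
  }
  check_number(shape_field, "shape_field", positive = TRUE)
  structure(list(ms = ms, mr = mr, hc = hc, shape_field = shape_field),
            class = "magnetic_material")
}

#' Parametric two-branch magnetization loop
#'
#' Branch model \eqn{M_\pm(H) = M_s \tanh((H \pm H_c)/H_s)}: the ascending
#' branch crosses zero at \eqn{+H_c} and passes through \eqn{-M_r} at zero
#' field; the descending branch mirrors it. With `mr = 0` the two branches
#' coincide in a single-valued anhysteretic curve.
#'
#' @param mat A [magnetic_material()].
#' @param h_grid Field grid (kA/m).
#' @return Data frame with columns `h`, `m_ascending`, `m_descending`
#'   (kA/m).
#' @examples
#' mat <- magnetic_material(388, 30, 6.2)
#' loop <- synthetic_loop(mat, seq(-200, 200, length.out = 401))
#' @export
synthetic_loop <- function(mat, h_grid) {
  stopifnot(inherits(mat, "magnetic_material"))
  if (any(!is.finite(h_grid)))
    stop_domain("'h_grid' must be finite (kA/m)")
  data.frame(h = h_grid,
             m_ascending = mat$ms * tanh((h_grid - mat$hc) / mat$shape_field),
             m_descending = mat$ms * tanh((h_grid + mat$hc) / mat$shape_field))
}

# Linear interpolation of the single sign change of `m` along `h`.
interp_zero_crossing <- function(h, m) {
  sgn <- sign(m)
  idx <- which(diff(sgn) != 0 | (sgn[-length(sgn)] == 0))
  if (length(idx) == 0) {
    if (any(m == 0)) return(h[which(m == 0)[1]])
    stop_domain("no zero crossing in the field range; widen 'h_grid'")
  }
  i <- idx[1]
  h[i] + (0 - m[i]) * (h[i + 1] - h[i]) / (m[i + 1] - m[i])
}

#' Extract loop parameters from a measured or synthetic loop
#'
#' Coercivity from the interpolated zero crossings of the two branches,
#' remanence from the branch values at zero field, and saturation
#' magnetization from the mean |M| over the top 5% of |H| refined by a
#' one-parameter solve of the tanh branch model at the largest measured
#' field (the crude tail mean underestimates \eqn{M_s} whenever the loop is
#' not fully saturated at the grid edge).
#'
#' @param h_grid Field grid (kA/m), covering both zero crossings and the
#'   near-saturation region.
#' @param m_ascending,m_descending Branch magnetizations (kA/m) on
#'   `h_grid`.
#' @return A [magnetic_material()] with the recovered parameters.
#' @examples
#' mat <- magnetic_material(388, 30, 6.2)
#' loop <- synthetic_loop(mat, seq(-200, 200, length.out = 2001))
#' extract_loop_params(loop$h, loop$m_ascending, loop$m_descending)
#' @export
extract_loop_params <- function(h_grid, m_ascending, m_descending) {
  stopifnot(length(h_grid) == length(m_ascending),
            length(h_grid) == length(m_descending))
  ord <- order(h_grid)
  h <- h_grid[ord]
  m_asc <- m_ascending[ord]
  m_desc <- m_descending[ord]

  h_asc0 <- interp_zero_crossing(h, m_asc)
  h_desc0 <- interp_zero_crossing(h, m_desc)
  hc <- (h_asc0 - h_desc0) / 2
  hc <- max(0, hc)

  m_asc_at0 <- stats::approx(h, m_asc, xout = 0)$y
  m_desc_at0 <- stats::approx(h, m_desc, xout = 0)$y
  mr <- max(0, (m_desc_at0 - m_asc_at0) / 2)

  tail_sel <- abs(h) >= stats::quantile(abs(h), 0.95)
  ms <- mean(c(abs(m_asc[tail_sel]), abs(m_desc[tail_sel])))

  # Model-based refinement: the tail mean underestimates Ms when the loop is
  # not saturated at the grid edge. Solve Ms tanh((Hmax - Hc)/Hs(Ms)) = M_obs
  # under the branch parameterization Hs = Hc/artanh(Mr/Ms).
  m_obs <- (abs(m_asc[length(m_asc)]) + abs(m_desc[1])) / 2
  h_max <- max(abs(h))
  if (hc > 1e-6 * h_max && mr > 0 && m_obs > mr) {
    f <- function(ms_try) {
      hs <- hc / atanh(min(mr / ms_try, 1 - 1e-12))
      ms_try * tanh((h_max - hc) / hs) - m_obs
    }
    refined <- tryCatch({
      stats::uniroot(f, lower = m_obs * (1 + 1e-9), upper = m_obs * 5,
                     tol = 1e-10)$root
    }, error = function(e) NULL)
    if (!is.null(refined)) ms <- refined
  }

  if (mr <= 1e-9 * ms) {
    slope0 <- stats::approx(h, (m_asc + m_desc) / 2, xout = 1e-3 * h_max)$y /
      (1e-3 * h_max)
    hs <- if (is.finite(slope0) && slope0 > 0) ms / slope0 else h_max
    magnetic_material(ms = ms, mr = 0, hc = 0, shape_field = hs)
  } else {
    magnetic_material(ms = ms, mr = mr, hc = hc)
  }
}
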