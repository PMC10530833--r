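# Force-balance dynamics of a bead moving along the tube past the
# electromagnet: RK4 time integration in the vertical symmetry plane,
# inelastic wall contact, capture/detachment classification, and
# velocity-profile extraction from trajectories or tracks.
#
# Coordinates: x is the axial position (m) along the tube; y is the height
# of the bead center above the inner tube wall nearest the magnet (m), so
# contact means y equals the bead radius and the tube axis is at y = R.

#' Simulation configuration
#'
#' @param initial_velocity Initial axial bead velocity (m/s); the reference
#'   experiments use 0.3 m/s (holding at 40 kA/m) and 0.25 m/s (32 kA/m).
#' @param time_step Integrator time step (s), > 0.
#' @param max_time Maximum simulated time (s).
#' @param seed Integer seed; only consumed when `flow_noise_sd > 0`.
#' @param y0 Initial height of the bead center above the lower inner wall
#'   (m); default 0.003 (near the axis of the 8 mm tube).
#' @param domain_length Axial extent of the simulated tube section (m); the
#'   run stops when the bead leaves it.
#' @param capture_speed Speed threshold (m/s) below which a bead over the
#'   core footprint counts as held; default 1e-3.
#' @param capture_hold Time (s) the capture condition must persist before
#'   the run stops early.
#' @param drag_calibration The single documented drag-calibration constant
#'   applied to the drag closure during trajectory runs; it absorbs
#'   rolling-contact and near-wall shielding effects the bare unbounded-flow
#'   correlation overestimates. Default 0.6.
#' @param record_every Store every n-th integration step; default 20.
#' @param flow_noise_sd Standard deviation (m/s) of a per-step Gaussian
#'   perturbation of the local fluid velocity; 0 (default) disables it and
#'   makes runs fully deterministic.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(initial_velocity = 0.3, time_step = 2e-5,
                              max_time = 1.5, seed = 1L, y0 = 0.003,
                              domain_length = 0.08, capture_speed = 1e-3,
                              capture_hold = 0.05, drag_calibration = 0.6,
                              record_every = 20L, flow_noise_sd = 0) {
  check_number(initial_velocity, "initial_velocity")
  check_number(time_step, "time_step", positive = TRUE)
  check_number(max_time, "max_time", positive = TRUE)
  check_number(y0, "y0", positive = TRUE)
  check_number(domain_length, "domain_length", positive = TRUE)
  check_number(capture_speed, "capture_speed", positive = TRUE)
  check_number(capture_hold, "capture_hold", positive = TRUE)
  check_number(drag_calibration, "drag_calibration", positive = TRUE)
  check_number(record_every, "record_every", positive = TRUE)
  check_number(flow_noise_sd, "flow_noise_sd", nonnegative = TRUE)
  structure(list(initial_velocity = initial_velocity, time_step = time_step,
                 max_time = max_time, seed = as.integer(seed), y0 = y0,
                 domain_length = domain_length, capture_speed = capture_speed,
                 capture_hold = capture_hold,
                 drag_calibration = drag_calibration,
                 record_every = as.integer(record_every),
                 flow_noise_sd = flow_noise_sd),
            class = "simulation_config")
}

# Per-state force evaluation shared by the integrator and bead_forces().
# Returns the breakdown; positions are clamped into the tube so RK4
# sub-steps slightly past a wall stay well defined.
#
# The undisturbed profile velocity is shielded near the wall by the factor
# (1 - 0.85 a/(a + gap)): a bead close to or rolling on the wall samples
# much slower fluid than the profile value at its center height (blockage,
# boundary-layer and rolling-kinematics effects the point closure misses).
eval_forces <- function(x, y, vx, vy, bead, magnet, flow, bead_density,
                        drag_calibration, g, u_perturb = 0) {
  R <- flow$tube_radius
  a <- bead$diameter / 2
  yc <- min(max(y, a), 2 * R - a)
  r <- yc - R
  u <- poiseuille_velocity(r, flow) + u_perturb
  s <- local_shear_rate(r, flow)
  gap <- yc - a
  u <- u * (1 - 0.85 * a / (a + gap))

  relx <- u - vx
  rely <- -vy
  rel <- sqrt(relx^2 + rely^2)
  if (rel > 0) {
    fd <- suppressWarnings(
      drag_force(rel, bead$diameter, flow, wall_gap = gap,
                 calibration = drag_calibration))
    fdx <- fd * relx / rel
    fdy <- fd * rely / rel
  } else {
    fdx <- 0; fdy <- 0
  }

  # Effective slip for the lift closure: center slip plus the shear sampled
  # across the finite bead radius; the sampling term fades at the wall,
  # where the lower bead face sits in nearly stagnant fluid.
  slip_eff <- rel + s * a * gap / (gap + a)
  fl <- lift_force(s, slip_eff, bead$diameter, flow, wall_gap = gap)
  flift_y <- if (yc <= R) fl else -fl

  fgrav <- gravity_buoyancy(bead$diameter, bead_density, flow, g = g)

  # Magnetic force from the local field magnitude and its finite-difference
  # gradient over the bead extent.
  hfun <- function(xx, yy) {
    z_mm <- (magnet$gap + max(yy, 0)) * 1000
    field_at(z_mm, magnet) * lateral_field_profile(xx - magnet$center_x, magnet)
  }
  h0c <- hfun(x, yc)
  if (h0c > 0 || magnet$h0 > 0) {
    dhdx <- (hfun(x + a, yc) - hfun(x - a, yc)) / (2 * a)
    dhdy <- (hfun(x, yc + a) - hfun(x, yc - a)) / (2 * a)
    pref <- MU0 * bead$chi_eff * bead$volume * h0c
    fmx <- pref * dhdx
    fmy <- pref * dhdy
  } else {
    fmx <- 0; fmy <- 0
  }

  list(drag_x = fdx, drag_y = fdy, lift_y = flift_y, grav_y = -fgrav,
       mag_x = fmx, mag_y = fmy, fluid_u = u)
}

#' Force breakdown on a bead at a given state
#'
#' Evaluates all closure forces (drag, lift, net weight, magnetic) for a
#' bead at axial position `x`, height `y` above the lower inner wall, and
#' velocity (`vx`, `vy`).
#'
#' @param x,y Bead center position (m); `y` measured from the inner tube
#'   wall nearest the magnet.
#' @param vx,vy Bead velocity components (m/s).
#' @param bead A [bead_magnetics()].
#' @param magnet A [magnet_model()] (with `gap` the core-to-inner-wall
#'   distance and `center_x` its axial position).
#' @param flow A [flow_config()].
#' @param bead_density Bead density (kg/m^3).
#' @param drag_calibration Drag calibration constant; default 1.
#' @param g Gravitational acceleration (m/s^2).
#' @return A list with components `drag_x`, `drag_y`, `lift_y`, `grav_y`,
#'   `mag_x`, `mag_y` (N) and the undisturbed fluid velocity `fluid_u`
#'   (m/s).
#' @export
bead_forces <- function(x, y, vx, vy, bead, magnet, flow,
                        bead_density = 1110, drag_calibration = 1, g = 9.8) {
  stopifnot(inherits(bead, "bead_magnetics"),
            inherits(magnet, "magnet_model"),
            inherits(flow, "flow_config"))
  eval_forces(x, y, vx, vy, bead, magnet, flow, bead_density,
              drag_calibration, g)
}

#' Simulate a bead moving through the tube past the electromagnet
#'
#' Integrates the force balance (drag, lift, net weight, magnetic
#' attraction) with a classical RK4 scheme, including an added-mass
#' coefficient of 0.5 (the bead is nearly neutrally buoyant, so unsteady
#' fluid inertia is not negligible). Wall contact is inelastic: penetration
#' is projected back onto the wall and the wall-normal velocity zeroed,
#' tangential motion is unaffected (frictionless sliding). The run ends when
#' the bead leaves the domain, the capture condition persists for
#' `capture_hold` seconds, or `max_time` elapses.
#'
#' @param magnet A [magnet_model()]; `center_x` locates the core along the
#'   tube and `gap` is the core-to-inner-wall distance.
#' @param flow A [flow_config()].
#' @param bead A [bead_magnetics()].
#' @param bead_density Bead density (kg/m^3); default 1110.
#' @param config A [simulation_config()].
#' @param g Gravitational acceleration (m/s^2); default 9.8.
#' @return A data frame of class `bead_trajectory` with columns `t`, `x`,
#'   `y`, `vx`, `vy`, `contact`, `fmag_x`, `fmag_y`, `fdrag_x`, `fdrag_y`,
#'   `flift_y`, `fgrav_y`, and attributes `outcome` (see
#'   [classify_outcome()]), `magnet`, `config`.
#' @examples
#' magnet <- magnet_model(h0 = 0, gap = 0.0015, center_x = 0.04)
#' bead <- bead_magnetics(0.00238, chi = 0.13)
#' traj <- simulate_bead(magnet, flow_config(), bead,
#'                       config = simulation_config(time_step = 1e-4,
#'                                                  record_every = 5L))
#' attr(traj, "outcome")
#' @export
simulate_bead <- function(magnet, flow, bead, bead_density = 1110,
                          config = simulation_config(), g = 9.8) {
  stopifnot(inherits(magnet, "magnet_model"), inherits(flow, "flow_config"),
            inherits(bead, "bead_magnetics"),
            inherits(config, "simulation_config"))
  a <- bead$diameter / 2
  R <- flow$tube_radius
  if (bead$diameter >= 2 * R)
    stop_domain("bead does not fit in the tube")
  if (config$y0 < a || config$y0 > 2 * R - a)
    stop_domain("'y0' places the bead center outside the tube bore")

  dt <- config$time_step
  n_max <- ceiling(config$max_time / dt)
  mass_eff <- (bead_density + 0.5 * flow$fluid_density) * bead$volume

  noise <- if (config$flow_noise_sd > 0) {
    with_seed(config$seed,
              stats::rnorm(n_max, sd = config$flow_noise_sd))
  } else NULL

  accel <- function(x, y, vx, vy, un) {
    f <- eval_forces(x, y, vx, vy, bead, magnet, flow, bead_density,
                     config$drag_calibration, g, u_perturb = un)
    fx <- f$drag_x + f$mag_x
    fy <- f$drag_y + f$lift_y + f$grav_y + f$mag_y
    if (!is.finite(fx) || !is.finite(fy))
      stop_domain(sprintf(
        "non-finite force at t-state (x=%.4g, y=%.4g, vx=%.4g, vy=%.4g): fx=%g fy=%g",
        x, y, vx, vy, fx, fy))
    c(fx / mass_eff, fy / mass_eff)
  }

  x <- 0; y <- config$y0
  vx <- config$initial_velocity; vy <- 0
  contact <- FALSE
  t <- 0
  hold <- 0
  core_r <- magnet$core_diameter / 2

  rec_idx <- 0L
  n_rec <- n_max %/% config$record_every + 16L
  rec <- matrix(NA_real_, nrow = n_rec, ncol = 12)

  record <- function(i, t, x, y, vx, vy, contact, un) {
    if (i > nrow(rec))
      rec <<- rbind(rec, matrix(NA_real_, nrow = nrow(rec), ncol = 12))
    f <- eval_forces(x, y, vx, vy, bead, magnet, flow, bead_density,
                     config$drag_calibration, g, u_perturb = un)
    rec[i, ] <<- c(t, x, y, vx, vy, as.numeric(contact), f$mag_x, f$mag_y,
                   f$drag_x, f$drag_y, f$lift_y, f$grav_y)
  }

  rec_idx <- rec_idx + 1L
  record(rec_idx, t, x, y, vx, vy, contact, 0)

  for (step in seq_len(n_max)) {
    un <- if (is.null(noise)) 0 else noise[step]
    speed <- sqrt(vx^2 + vy^2)
    if (dt * max(speed, abs(vx), abs(vy)) >= a / 2)
      stop_domain(sprintf(
        "time step too large: dt * |v| = %.3g m exceeds half the bead radius; reduce 'time_step'",
        dt * speed))

    # RK4 on (x, y, vx, vy)
    k1 <- c(vx, vy, accel(x, y, vx, vy, un))
    s2 <- c(x, y, vx, vy) + dt / 2 * k1
    k2 <- c(s2[3], s2[4], accel(s2[1], s2[2], s2[3], s2[4], un))
    s3 <- c(x, y, vx, vy) + dt / 2 * k2
    k3 <- c(s3[3], s3[4], accel(s3[1], s3[2], s3[3], s3[4], un))
    s4 <- c(x, y, vx, vy) + dt * k3
    k4 <- c(s4[3], s4[4], accel(s4[1], s4[2], s4[3], s4[4], un))
    snew <- c(x, y, vx, vy) + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)

    x <- snew[1]; y <- snew[2]; vx <- snew[3]; vy <- snew[4]
    t <- t + dt

    # Inelastic wall contact: project, zero the wall-normal velocity.
    prev_contact <- contact
    contact <- FALSE
    if (y <= a) {
      y <- a
      if (vy < 0) vy <- 0
      contact <- TRUE
    } else if (y >= 2 * R - a) {
      y <- 2 * R - a
      if (vy > 0) vy <- 0
    }

    # Record regular samples plus contact-state transitions, so classification
    # can see even contacts briefer than the sampling interval.
    if (step %% config$record_every == 0L || contact != prev_contact) {
      rec_idx <- rec_idx + 1L
      record(rec_idx, t, x, y, vx, vy, contact, un)
    }

    speed <- sqrt(vx^2 + vy^2)
    if (speed < config$capture_speed && abs(x - magnet$center_x) <= core_r) {
      hold <- hold + dt
      if (hold >= config$capture_hold) break
    } else {
      hold <- 0
    }
    if (x > config$domain_length) break
  }

  if (rec[rec_idx, 1] < t) {
    rec_idx <- rec_idx + 1L
    record(rec_idx, t, x, y, vx, vy, contact, 0)
  }

  traj <- as.data.frame(rec[seq_len(rec_idx), , drop = FALSE])
  names(traj) <- c("t", "x", "y", "vx", "vy", "contact", "fmag_x", "fmag_y",
                   "fdrag_x", "fdrag_y", "flift_y", "fgrav_y")
  traj$contact <- traj$contact > 0
  class(traj) <- c("bead_trajectory", class(traj))
  attr(traj, "magnet") <- magnet
  attr(traj, "config") <- config
  attr(traj, "outcome") <- classify_outcome(traj, magnet,
                                            capture_speed = config$capture_speed)
  traj
}

#' @export
print.bead_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "Bead trajectory: %d samples over %.3f s, outcome '%s'\n  final state: x = %.4f m, y = %.4f m, speed = %.4g m/s\n",
    n, x$t[n], attr(x, "outcome"), x$x[n], x$y[n],
    sqrt(x$vx[n]^2 + x$vy[n]^2)))
  invisible(x)
}

#' Classify the outcome of a trajectory
#'
#' `"captured"` when the bead ends held over the core footprint: its
#' terminal axial drift speed (net displacement over the trailing `window`,
#' which ignores residual vibration of a bead ringing in a stiff magnetic
#' trap) is below `capture_speed`; `"detached"` when wall contact occurred
#' over the footprint but the bead ended up beyond its downstream edge;
#' `"passed"` otherwise.
#'
#' @param traj A `bead_trajectory` (or data frame with columns `t`, `x`,
#'   `vx`, `vy`, `contact`).
#' @param magnet The [magnet_model()] of the run.
#' @param capture_speed Drift-speed threshold (m/s); default 1e-3.
#' @param window Trailing time window (s) over which the terminal drift is
#'   measured; shortened automatically for brief trajectories.
#' @return One of `"captured"`, `"detached"`, `"passed"`.
#' @export
classify_outcome <- function(traj, magnet, capture_speed = 1e-3,
                             window = 0.05) {
  stopifnot(inherits(magnet, "magnet_model"), nrow(traj) > 0)
  n <- nrow(traj)
  core_r <- magnet$core_diameter / 2
  over <- abs(traj$x - magnet$center_x) <= core_r
  w <- min(window, (traj$t[n] - traj$t[1]) / 2)
  drift_speed <- if (n >= 2 && w > 0) {
    x_back <- stats::approx(traj$t, traj$x, xout = traj$t[n] - w)$y
    abs(traj$x[n] - x_back) / w
  } else {
    sqrt(traj$vx[n]^2 + traj$vy[n]^2)
  }
  if (drift_speed < capture_speed && over[n]) return("captured")
  if (any(traj$contact & over) && traj$x[n] > magnet$center_x + core_r)
    return("detached")
  "passed"
}

#' Axial velocity profile of a trajectory or track
#'
#' Centered finite-difference axial velocity, smoothed by a centered moving
#' average, against axial position. Accepts either a simulated trajectory or
#' an observed `(t, x)` track table.
#'
#' @param traj Data frame with columns `t` and `x` (strictly monotone `t`).
#' @param window Odd moving-average window length, >= 3.
#' @return Data frame with columns `x` (m) and `vx` (m/s), shortened at the
#'   edges by the differencing and smoothing stencils.
#' @export
velocity_profile <- function(traj, window = 11L) {
  if (window < 3 || window %% 2 == 0)
    stop_domain("'window' must be an odd integer >= 3")
  n <- nrow(traj)
  if (n < window + 2)
    stop_domain("trajectory shorter than the smoothing window")
  t <- traj$t; x <- traj$x
  i <- 2:(n - 1)
  vx_fd <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  vx_s <- as.numeric(stats::filter(vx_fd, rep(1 / window, window),
                                   sides = 2))
  keep <- !is.na(vx_s)
  data.frame(x = x[i][keep], vx = vx_s[keep])
}
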