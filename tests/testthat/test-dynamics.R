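# Trajectory tests use reduced domains and coarser steps than the reference
# runs so the suite stays fast; the reference-condition runs live in the
# acceptance tests.

quiescent <- function(R = 0.05) {
  flow_config(tube_radius = R, mean_velocity = 0)
}

test_that("neutrally buoyant bead in equilibrium stays on the centerline", {
  fl <- flow_config()
  bead <- ref_bead()
  magnet <- magnet_model(h0 = 0, gap = 0.0015, center_x = 10)
  f0 <- bead_forces(0, fl$tube_radius, 0, 0, bead, magnet, fl,
                    bead_density = fl$fluid_density)
  cfg <- simulation_config(initial_velocity = f0$fluid_u, time_step = 5e-5,
                           max_time = 0.05, y0 = fl$tube_radius,
                           domain_length = 1)
  traj <- simulate_bead(magnet, fl, bead, bead_density = fl$fluid_density,
                        config = cfg)
  expect_lt(max(abs(traj$y - fl$tube_radius)), 1e-9)
  expect_lt(max(abs(traj$vx - f0$fluid_u)), 1e-9)
  expect_true(all(diff(traj$x) > 0))
})

test_that("quiescent settling converges to the terminal velocity", {
  fl <- quiescent()
  bead <- ref_bead()
  magnet <- magnet_model(h0 = 0, gap = 0.0015, center_x = 10)
  cfg <- simulation_config(initial_velocity = 0, time_step = 1e-4,
                           max_time = 0.5, y0 = 0.045, domain_length = 1,
                           drag_calibration = 1)
  traj <- simulate_bead(magnet, fl, bead, config = cfg)
  vt <- oracle_terminal_velocity(bead$diameter, 1110, fl$fluid_density,
                                 fl$viscosity)
  expect_equal(max(abs(traj$vy)), vt, tolerance = 0.02)
  expect_true(all(diff(traj$y) <= 0))
})

test_that("kinetic energy decays without magnet, inflow or weight", {
  fl <- quiescent()
  bead <- ref_bead()
  magnet <- magnet_model(h0 = 0, gap = 0.0015, center_x = 10)
  cfg <- simulation_config(initial_velocity = 0.2, time_step = 1e-4,
                           max_time = 0.3, y0 = 0.025, domain_length = 1)
  traj <- simulate_bead(magnet, fl, bead, bead_density = fl$fluid_density,
                        config = cfg)
  ke <- traj$vx^2 + traj$vy^2
  expect_true(all(diff(ke) <= 1e-12))
  expect_lt(ke[length(ke)], 0.05 * ke[1])
})

test_that("no magnet means monotone passage; an extreme field captures", {
  fl <- flow_config()
  bead <- ref_bead()
  cfg <- simulation_config(time_step = 2e-5, max_time = 0.5,
                           domain_length = 0.05)
  off <- simulate_bead(magnet_model(h0 = 0, gap = 0.0015, center_x = 0.025),
                       fl, bead, config = cfg)
  expect_identical(attr(off, "outcome"), "passed")
  expect_true(all(diff(off$x) > 0))
  strong <- simulate_bead(ref_magnet(430, center_x = 0.025), fl, bead,
                          config = cfg)
  expect_identical(attr(strong, "outcome"), "captured")
})

test_that("halving the time step leaves the trajectory unchanged within 1%", {
  fl <- flow_config()
  bead <- ref_bead()
  magnet <- ref_magnet(24, center_x = 0.02)
  run <- function(dt) {
    cfg <- simulation_config(time_step = dt, max_time = 0.4,
                             domain_length = 0.04, record_every = 50L)
    simulate_bead(magnet, fl, bead, config = cfg)
  }
  t1 <- run(4e-5); t2 <- run(2e-5)
  n1 <- nrow(t1); n2 <- nrow(t2)
  expect_lt(abs(t1$y[n1] - t2$y[n2]) / t2$y[n2], 0.01)
  expect_lt(abs(t1$vx[n1] - t2$vx[n2]) / abs(t2$vx[n2]), 0.01)
  expect_identical(attr(t1, "outcome"), attr(t2, "outcome"))
})

test_that("outcome is invariant to finer trajectory sampling", {
  fl <- flow_config()
  bead <- ref_bead()
  for (h0 in c(0, 430)) {
    magnet <- ref_magnet(h0, center_x = 0.025)
    outs <- vapply(c(20L, 5L), function(re) {
      cfg <- simulation_config(time_step = 2e-5, max_time = 0.5,
                               domain_length = 0.05, record_every = re)
      attr(simulate_bead(magnet, fl, bead, config = cfg), "outcome")
    }, character(1))
    expect_identical(outs[1], outs[2])
  }
})

test_that("the integrator rejects reckless time steps", {
  fl <- flow_config()
  bead <- ref_bead()
  magnet <- magnet_model(h0 = 0, gap = 0.0015, center_x = 10)
  cfg <- simulation_config(initial_velocity = 0.3, time_step = 0.005,
                           max_time = 0.1)
  expect_error(simulate_bead(magnet, fl, bead, config = cfg), "time step")
})

test_that("outcome classification follows the final state and contact history", {
  magnet <- ref_magnet(40, center_x = 0.04)
  still <- data.frame(t = 0:2, x = 0.041, y = 0.00119, vx = 0, vy = 0,
                      contact = TRUE)
  expect_identical(classify_outcome(still, magnet), "captured")
  rolled <- data.frame(t = 0:3, x = c(0.035, 0.045, 0.055, 0.07),
                       y = 0.00119, vx = 0.2, vy = 0,
                       contact = c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(classify_outcome(rolled, magnet), "detached")
  fast <- data.frame(t = 0:3, x = c(0.02, 0.04, 0.06, 0.08), y = 0.003,
                     vx = 0.32, vy = 0, contact = FALSE)
  expect_identical(classify_outcome(fast, magnet), "passed")
})

test_that("velocity profile recovers uniform motion and flips with reversal", {
  t <- seq(0, 1, by = 1e-3)
  traj <- data.frame(t = t, x = 0.05 + 0.3 * t)
  vp <- velocity_profile(traj, window = 11)
  expect_lt(max(abs(vp$vx - 0.3)), 1e-9)
  rev_traj <- data.frame(t = t, x = rev(traj$x))
  vp_rev <- velocity_profile(rev_traj, window = 11)
  expect_lt(max(abs(vp_rev$vx + 0.3)), 1e-9)
  expect_error(velocity_profile(traj, window = 10), "odd")
  expect_error(velocity_profile(traj[1:8, ], window = 11), "shorter")
})
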