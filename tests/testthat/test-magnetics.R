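test_that("axial field law decays linearly and clamps at zero", {
  m <- magnet_model(h0 = 43e3)
  expect_equal(field_at(0, m), 43e3)
  expect_equal(field_at(4, m), 43e3 * (1 - 0.073 * 4))
  expect_equal(field_at(1 / 0.073 + 1, m), 0)
  expect_error(field_at(-1, m), ">= 0")
})

test_that("lateral field profile is even, monotone and footprint-bounded", {
  m <- magnet_model(h0 = 40e3)
  expect_equal(lateral_field_profile(0, m), 1)
  xs <- seq(0, 0.03, by = 1e-3)
  w <- lateral_field_profile(xs, m)
  expect_true(all(diff(w) < 0))
  expect_equal(lateral_field_profile(-xs, m), w)
  expect_lte(lateral_field_profile(1.5 * m$core_diameter / 2, m), 0.05)
  expect_lt(lateral_field_profile(0.02, m), 0.05)
})

test_that("single-bead force matches the volume-integral oracle", {
  bead <- ref_bead()
  for (h0_ka in c(21.5, 29.4, 37.4)) {
    m <- magnet_model(h0 = h0_ka * 1000, gap = 0.004)
    f_closed <- bead_attraction_force(bead, m)
    f_oracle <- oracle_sphere_force(h0_ka * 1000, chi = 0.13,
                                    diameter = 0.00238, gap_m = 0.004,
                                    decay_per_mm = 0.073)
    expect_lt(abs(f_closed - f_oracle) / f_oracle, 0.05)
  }
})

test_that("single-bead force limits and sign behave as the field dictates", {
  b0 <- bead_magnetics(0.00238, chi = 0)
  expect_equal(single_bead_force(b0, 1e4, 2e4), 0)
  b <- ref_bead()
  expect_equal(single_bead_force(b, 2e4, 2e4), 0)
  expect_lt(single_bead_force(b, 2e4, 1e4), 0)  # bead above the field maximum
  # non-interacting prediction is well below the per-bead array measurement
  m <- magnet_model(h0 = 37.4e3, gap = 0.004)
  expect_lt(bead_attraction_force(b, m), 0.178e-3)
  expect_equal(bead_attraction_force(b, m), 7.0e-5, tolerance = 0.02)
})

test_that("force increases with field, susceptibility and bead volume", {
  geom <- array_geometry(0.00238, correction_level = "none")
  m <- magnet_model(h0 = 0, gap = 0.004)
  curve <- array_force_curve(ref_bead(), m, geom, h0_grid = seq(0, 43, 1))
  expect_true(all(diff(curve$force_N) > 0))
  f_chi <- vapply(c(0.05, 0.1, 0.2, 0.4), function(chi)
    bead_attraction_force(bead_magnetics(0.00238, chi),
                          magnet_model(h0 = 40e3, gap = 0.004)), numeric(1))
  expect_true(all(diff(f_chi) > 0))
  f_d <- vapply(c(1e-3, 2e-3, 3e-3), function(d)
    bead_attraction_force(bead_magnetics(d, 0.13),
                          magnet_model(h0 = 40e3, gap = 0.004)), numeric(1))
  expect_true(all(diff(f_d) > 0))
})

test_that("dipole correction field follows the inverse-cube neighbor law", {
  expect_equal(dipole_correction_field(1, 0.1, 1), 2 / (4 * pi * 1e-3),
               tolerance = 1e-10)
  expect_equal(dipole_correction_field(3, 0.05, 2),
               dipole_correction_field(3, 0.05, 1) / 8)
  expect_equal(dipole_correction_field(0, 0.1, 1), 0)
  expect_error(dipole_correction_field(1, 0, 1), "spacing")
})

test_that("array force curves respect correction-level ordering", {
  bead <- ref_bead()
  m <- magnet_model(h0 = 0, gap = 0.004)
  grid <- seq(0, 43, by = 1)
  levels <- c("none", "first", "first_and_second")
  curves <- lapply(levels, function(lv)
    array_force_curve(bead, m, array_geometry(0.00238, correction_level = lv),
                      h0_grid = grid))
  names(curves) <- levels
  expect_true(all(curves$first_and_second$force_N >= curves$first$force_N))
  expect_true(all(curves$first$force_N >= curves$none$force_N))
  expect_gt(curves$first$force_N[44], curves$none$force_N[44])
  # level "none" reproduces the single-bead force pointwise
  f_single <- vapply(grid, function(h0)
    bead_attraction_force(bead, magnet_model(h0 = h0 * 1000, gap = 0.004)),
    numeric(1))
  expect_equal(curves$none$force_N, f_single, tolerance = 1e-12)
})

test_that("array corrections vanish for zero susceptibility and wide spacing", {
  m <- magnet_model(h0 = 0, gap = 0.004)
  grid <- seq(0, 43, by = 4.3)
  for (lv in c("none", "first", "first_and_second")) {
    cz <- array_force_curve(bead_magnetics(0.00238, 0), m,
                            array_geometry(0.00238, correction_level = lv),
                            h0_grid = grid)
    expect_true(all(cz$force_N == 0))
  }
  wide <- array_force_curve(ref_bead(), m,
                            array_geometry(1, correction_level = "first_and_second"),
                            h0_grid = grid)
  near <- array_force_curve(ref_bead(), m,
                            array_geometry(0.00238, correction_level = "none"),
                            h0_grid = grid)
  expect_equal(wide$force_N, near$force_N, tolerance = 1e-6)
})

test_that("force scales quadratically with the surface field", {
  bead <- ref_bead()
  m <- magnet_model(h0 = 0, gap = 0.004)
  grid <- seq(1, 43, by = 2)
  for (lv in c("none", "first", "first_and_second")) {
    curve <- array_force_curve(bead, m,
                               array_geometry(0.00238, correction_level = lv),
                               h0_grid = grid)
    ratio <- curve$force_N / grid^2
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  }
})

test_that("tanh loop passes through coercive and remanence points", {
  mat <- magnetic_material(388, 30, 6.2)
  expect_equal(mat$shape_field, 6.2 / atanh(30 / 388), tolerance = 1e-12)
  expect_equal(mat$shape_field, 80.0, tolerance = 1e-3)
  loop <- synthetic_loop(mat, c(-6.2, 0, 6.2))
  expect_equal(loop$m_ascending[3], 0)
  expect_equal(loop$m_descending[1], 0)
  expect_equal(loop$m_ascending[2], -30, tolerance = 1e-10)
  expect_equal(loop$m_descending[2], 30, tolerance = 1e-10)
  an <- magnetic_material(388, 0, 0, shape_field = 80)
  loop2 <- synthetic_loop(an, seq(-100, 100, 10))
  expect_equal(loop2$m_ascending, loop2$m_descending)
  expect_error(magnetic_material(388, 400, 6.2), "'mr'")
  expect_error(magnetic_material(388, 0, 6.2), "anhysteretic")
})

test_that("loop-parameter extraction round-trips the generating material", {
  mat <- magnetic_material(388, 30, 6.2)
  loop <- synthetic_loop(mat, seq(-200, 200, length.out = 2001))
  rec <- extract_loop_params(loop$h, loop$m_ascending, loop$m_descending)
  expect_lt(abs(rec$hc - 6.2) / 6.2, 0.005)
  expect_lt(abs(rec$ms - 388) / 388, 0.005)
  expect_lt(abs(rec$mr - 30) / 30, 0.005)
  an <- magnetic_material(388, 0, 0, shape_field = 80)
  la <- synthetic_loop(an, seq(-200, 200, length.out = 1001))
  rec2 <- extract_loop_params(la$h, la$m_ascending, la$m_descending)
  expect_equal(rec2$hc, 0)
  expect_equal(rec2$mr, 0)
  expect_error(
    extract_loop_params(seq(50, 200, 1),
                        388 * tanh((seq(50, 200, 1) - 6.2) / 80),
                        388 * tanh((seq(50, 200, 1) + 6.2) / 80)),
    "zero crossing")
})

test_that("anhysteretic loop slope ties the filler loop to the bead susceptibility", {
  mat <- magnetic_material(388, 30, 6.2)
  phi <- gel_composition(alpha = 4.5, loss_hg = 86.32, loss_fg = 26.07)$phi
  chi0 <- phi * mat$ms / mat$shape_field
  expect_equal(chi0, 0.13, tolerance = 0.05)
})
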