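# Independent oracles used across test files. These deliberately avoid the
# package's closed-form code paths.

# Brute-force magnetostatic force on a sphere in the linear axial field:
# midpoint-rule volume integral of mu0 chi_eff H (dH/dz) over the sphere,
# sliced perpendicular to the field gradient.
oracle_sphere_force <- function(h0, chi, diameter, gap_m, decay_per_mm,
                                demag = 1 / 3, n_slices = 2000) {
  mu0 <- 4e-7 * pi
  chi_eff <- chi / (1 + demag * chi)
  a <- diameter / 2
  zc <- gap_m + a                      # sphere center distance from core (m)
  dz <- diameter / n_slices
  z <- gap_m + (seq_len(n_slices) - 0.5) * dz   # slice centers (m)
  area <- pi * (a^2 - (z - zc)^2)
  h <- pmax(0, h0 * (1 - decay_per_mm * z * 1000))
  dhdz <- ifelse(h > 0, -h0 * decay_per_mm * 1000, 0)
  # force toward the magnet (decreasing z), hence the minus sign
  -sum(mu0 * chi_eff * h * dhdz * area * dz)
}

# Terminal settling velocity by damped fixed-point iteration on the
# Schiller-Naumann force balance (independent of the package's root finder).
oracle_terminal_velocity <- function(diameter, bead_density, fluid_density,
                                     viscosity, g = 9.8) {
  w <- (bead_density - fluid_density) * pi / 6 * diameter^3 * g
  area <- pi / 4 * diameter^2
  v <- 0.01
  for (i in 1:500) {
    re <- fluid_density * v * diameter / viscosity
    cd <- 24 / re * (1 + 0.15 * re^0.687)
    v_new <- sqrt(w / (0.5 * cd * fluid_density * area))
    v <- 0.5 * v + 0.5 * v_new
  }
  v
}

# Reference bead/flow/magnet objects for the study conditions.
ref_bead <- function() bead_magnetics(0.00238, chi = 0.13)
ref_flow <- function() flow_config()
ref_magnet <- function(h0_ka, center_x = 0.04) {
  magnet_model(h0 = h0_ka * 1000, gap = 0.0015, center_x = center_x)
}
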