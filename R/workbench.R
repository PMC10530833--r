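# Configuration, file I/O and pipeline orchestration: a single structured
# YAML config with per-section defaults matching the reference experiment,
# and commands that write delimited text tables with provenance headers.

#' Default run configuration
#'
#' Nested list of all pipeline parameters with defaults equal to the
#' reference experiment: gel composition inputs, electromagnet calibration,
#' array geometry, tube flow, simulation settings, bead properties and
#' synthetic-data parameters.
#'
#' @return A named nested list (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    material = list(
      alpha = 4.5, loss_hg = 86.32, loss_fg = 26.07,
      rho_gel = 1110, rho_particle = 5180,
      chi_ref = 0.408, phi_ref = 0.0957, chi_override = 0.13),
    magnet = list(
      h0_kA_m = 40, decay_coeff = 0.073, core_diameter = 0.018,
      gap = 0.0015, center_x = 0.04),
    array = list(
      lattice_spacing = 0.00238, n_first = 2, n_second = 2,
      correction_level = "first"),
    flow = list(
      tube_radius = 0.004, mean_velocity = 0.32, viscosity = 0.00102,
      fluid_density = 1000, profile = "laminar"),
    bead = list(diameter = 0.00238, density = 1110,
                demag_factor = 1 / 3),
    dynamics = list(
      initial_velocity = 0.3, time_step = 2e-5, max_time = 1.5,
      y0 = 0.003, domain_length = 0.08, capture_speed = 0.001,
      capture_hold = 0.05, drag_calibration = 0.6, record_every = 20,
      flow_noise_sd = 0),
    synth = list(
      psd_median_nm = 248, psd_dispersion_nm = 57, psd_n = 10000,
      bead_mean_diameter_mm = 2.37, bead_sd_mm = 0.12, bead_n = 100,
      track_position_sd = 1e-5, frame_rate = 1000)
  ), class = "run_config")
}

# Keys that must be strictly positive / nonnegative when present.
.positive_keys <- c("alpha", "loss_hg", "loss_fg", "rho_gel", "rho_particle",
                    "chi_ref", "phi_ref", "decay_coeff", "core_diameter",
                    "lattice_spacing", "tube_radius", "viscosity",
                    "fluid_density", "diameter", "density", "time_step",
                    "max_time", "y0", "domain_length", "capture_speed",
                    "capture_hold", "drag_calibration", "record_every",
                    "psd_median_nm", "psd_n", "bead_mean_diameter_mm",
                    "bead_n", "frame_rate")
.nonnegative_keys <- c("h0_kA_m", "gap", "chi_override", "n_first",
                       "n_second", "mean_velocity", "demag_factor",
                       "flow_noise_sd", "psd_dispersion_nm", "bead_sd_mm",
                       "track_position_sd")

validate_config <- function(config) {
  defaults <- default_run_config()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0)
    stop_domain("unknown config section(s): ", paste(bad, collapse = ", "))
  for (section in names(config)) {
    bad <- setdiff(names(config[[section]]), names(defaults[[section]]))
    if (length(bad) > 0)
      stop_domain(sprintf("unknown key(s) in section '%s': %s", section,
                          paste(bad, collapse = ", ")))
    for (key in names(config[[section]])) {
      val <- config[[section]][[key]]
      if (is.numeric(val)) {
        if (!all(is.finite(val)))
          stop_domain(sprintf("config %s:%s must be finite", section, key))
        if (key %in% .positive_keys && any(val <= 0))
          stop_domain(sprintf("config %s:%s must be > 0 (got %g)",
                              section, key, val))
        if (key %in% .nonnegative_keys && any(val < 0))
          stop_domain(sprintf("config %s:%s must be >= 0 (got %g)",
                              section, key, val))
      }
    }
  }
  invisible(config)
}

merge_config <- function(defaults, override) {
  for (section in names(override)) {
    for (key in names(override[[section]])) {
      defaults[[section]][[key]] <- override[[section]][[key]]
    }
  }
  defaults
}

#' Load a run configuration from a YAML file
#'
#' Reads the file, validates every section and key against the schema of
#' [default_run_config()] (unknown keys are rejected, physical parameters
#' must be positive), and fills unset values with the defaults. An empty
#' file yields the full default configuration.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_domain("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
  config <- merge_config(default_run_config(), user)
  validate_config(config)
  class(config) <- "run_config"
  config
}

#' Save a run configuration to a YAML file
#'
#' @param config A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

config_fingerprint <- function(config) {
  poly_hash(yaml::as.yaml(unclass(config)))
}

write_output_table <- function(df, path, command, config, seed) {
  header <- c(
    sprintf("# ferrobead %s",
            as.character(utils::packageVersion("ferrobead"))),
    sprintf("# command: %s", command),
    sprintf("# seed: %d", as.integer(seed)),
    sprintf("# config_hash: %s", config_fingerprint(config)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline output table
#'
#' Reads a comma-separated table written by [run_pipeline()], skipping the
#' provenance header lines.
#'
#' @param path Path to the table.
#' @return A data frame.
#' @export
read_output_table <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

config_to_objects <- function(config) {
  list(
    bead = bead_magnetics(config$bead$diameter,
                          chi = if (!is.null(config$material$chi_override))
                            config$material$chi_override
                          else gel_composition(
                            alpha = config$material$alpha,
                            loss_hg = config$material$loss_hg,
                            loss_fg = config$material$loss_fg,
                            rho_gel = config$material$rho_gel,
                            rho_particle = config$material$rho_particle,
                            chi_ref = config$material$chi_ref,
                            phi_ref = config$material$phi_ref)$chi,
                          demag_factor = config$bead$demag_factor),
    magnet = magnet_model(h0 = config$magnet$h0_kA_m * 1000,
                          decay_coeff = config$magnet$decay_coeff,
                          core_diameter = config$magnet$core_diameter,
                          gap = config$magnet$gap,
                          center_x = config$magnet$center_x),
    flow = flow_config(tube_radius = config$flow$tube_radius,
                       mean_velocity = config$flow$mean_velocity,
                       viscosity = config$flow$viscosity,
                       fluid_density = config$flow$fluid_density,
                       profile = config$flow$profile),
    geom = array_geometry(config$array$lattice_spacing,
                          n_first = config$array$n_first,
                          n_second = config$array$n_second,
                          correction_level = config$array$correction_level),
    sim = simulation_config(
      initial_velocity = config$dynamics$initial_velocity,
      time_step = config$dynamics$time_step,
      max_time = config$dynamics$max_time, y0 = config$dynamics$y0,
      domain_length = config$dynamics$domain_length,
      capture_speed = config$dynamics$capture_speed,
      capture_hold = config$dynamics$capture_hold,
      drag_calibration = config$dynamics$drag_calibration,
      record_every = config$dynamics$record_every,
      flow_noise_sd = config$dynamics$flow_noise_sd)
  )
}

#' Run a pipeline command
#'
#' Executes one stage of the modelling pipeline and writes its results as
#' comma-separated tables (dot decimal, header row) with a provenance
#' header (package version, command, seed, config fingerprint). Outputs are
#' deterministic for a fixed configuration and seed.
#'
#' Commands:
#' * `"composition"` — the full composition chain; writes
#'   `composition.csv`.
#' * `"force-curve"` — per-bead force over 0 to 43 kA/m at the configured
#'   correction level; writes `force_curve.csv`.
#' * `"simulate"` — trajectory run; writes `trajectory.csv` and
#'   `summary.csv` (outcome, final state).
#' * `"synth"` — synthetic PSD, magnetization loop and bead population;
#'   writes `psd.csv`, `loop.csv`, `beads.csv`.
#' * `"analyze-track"` — velocity profile of a `(t, x)` track table;
#'   requires `track_file`, writes `velocity_profile.csv`.
#'
#' @param command One of the commands above.
#' @param config A `run_config` list; default [default_run_config()].
#' @param out_dir Output directory; created if missing.
#' @param seed Integer seed forwarded to every stochastic generator.
#' @param track_file Path of the track table for `"analyze-track"`.
#' @param window Smoothing window for `"analyze-track"`; default 11.
#' @return Character vector of the files written, invisibly.
#' @export
run_pipeline <- function(command = c("composition", "force-curve",
                                     "simulate", "synth", "analyze-track"),
                         config = default_run_config(), out_dir = ".",
                         seed = 1L, track_file = NULL, window = 11L) {
  command <- match.arg(command)
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  obj <- config_to_objects(config)
  written <- character(0)
  out <- function(name) file.path(out_dir, name)

  if (command == "composition") {
    comp <- gel_composition(
      alpha = config$material$alpha, loss_hg = config$material$loss_hg,
      loss_fg = config$material$loss_fg, rho_gel = config$material$rho_gel,
      rho_particle = config$material$rho_particle,
      chi_ref = config$material$chi_ref, phi_ref = config$material$phi_ref,
      chi_override = config$material$chi_override)
    df <- data.frame(
      alpha = comp$alpha, gamma = comp$gamma,
      alpha_prime = comp$alpha_prime, omega_percent = 100 * comp$omega,
      phi_percent = 100 * comp$phi, chi_chain = comp$chi_chain,
      chi = comp$chi)
    write_output_table(df, out("composition.csv"), command, config, seed)
    written <- out("composition.csv")
  } else if (command == "force-curve") {
    curve <- array_force_curve(obj$bead, obj$magnet, obj$geom,
                               h0_grid = seq(0, 43, by = 0.5))
    df <- data.frame(h0_kA_m = curve$h0_kA_m, force_N = curve$force_N,
                     correction_level = attr(curve, "correction_level"))
    write_output_table(df, out("force_curve.csv"), command, config, seed)
    written <- out("force_curve.csv")
  } else if (command == "simulate") {
    sim <- obj$sim
    sim$seed <- as.integer(seed)
    traj <- simulate_bead(obj$magnet, obj$flow, obj$bead,
                          bead_density = config$bead$density, config = sim)
    df <- data.frame(t_s = traj$t, x_m = traj$x, y_m = traj$y,
                     vx_m_s = traj$vx, vy_m_s = traj$vy,
                     contact = as.integer(traj$contact),
                     Fmag_x_N = traj$fmag_x, Fmag_y_N = traj$fmag_y,
                     Fdrag_x_N = traj$fdrag_x, Flift_y_N = traj$flift_y)
    write_output_table(df, out("trajectory.csv"), command, config, seed)
    n <- nrow(traj)
    summary_df <- data.frame(
      outcome = attr(traj, "outcome"), t_final_s = traj$t[n],
      x_final_m = traj$x[n], y_final_m = traj$y[n],
      speed_final_m_s = sqrt(traj$vx[n]^2 + traj$vy[n]^2))
    write_output_table(summary_df, out("summary.csv"), command, config, seed)
    written <- c(out("trajectory.csv"), out("summary.csv"))
  } else if (command == "synth") {
    sy <- config$synth
    psd <- sample_psd(sy$psd_n, median = sy$psd_median_nm,
                      dispersion = sy$psd_dispersion_nm, seed = seed)
    write_output_table(data.frame(diameter_nm = psd), out("psd.csv"),
                       command, config, seed)
    mat <- magnetic_material(388, 30, 6.2)
    loop <- synthetic_loop(mat, seq(-200, 200, length.out = 2001))
    write_output_table(loop, out("loop.csv"), command, config, seed)
    beads <- generate_bead_population(sy$bead_n,
                                      mean_diameter = sy$bead_mean_diameter_mm,
                                      sd = sy$bead_sd_mm, seed = seed)
    write_output_table(data.frame(diameter_mm = beads), out("beads.csv"),
                       command, config, seed)
    written <- c(out("psd.csv"), out("loop.csv"), out("beads.csv"))
  } else if (command == "analyze-track") {
    if (is.null(track_file) || !file.exists(track_file))
      stop_domain("'analyze-track' needs an existing 'track_file'")
    track <- read_output_table(track_file)
    if (!all(c("t", "x") %in% names(track)))
      stop_domain("track file must have columns 't' and 'x'")
    prof <- velocity_profile(track, window = window)
    write_output_table(prof, out("velocity_profile.csv"), command, config,
                       seed)
    written <- out("velocity_profile.csv")
  }
  invisible(written)
}
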