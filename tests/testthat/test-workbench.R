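# Fast study-condition overrides for pipeline runs: a short tube section and
# a coarser integrator keep these I/O tests quick.
fast_sim_config <- function(h0_kA_m = 0) {
  config <- default_run_config()
  config$magnet$h0_kA_m <- h0_kA_m
  config$magnet$center_x <- 0.015
  config$dynamics$domain_length <- 0.03
  config$dynamics$max_time <- 0.3
  config$dynamics$time_step <- 5e-5
  config
}

test_that("an empty config file yields the full defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(character(0), path)
  config <- load_config(path)
  expect_equal(unclass(config), unclass(default_run_config()))
  expect_equal(config$flow$viscosity, 0.00102)
  expect_equal(config$bead$diameter, 0.00238)
})

test_that("schema violations are rejected with the offending keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("flow:\n  viscosity: -1", path)
  expect_error(load_config(path), "viscosity")
  writeLines("flow:\n  viscocity: 0.001", path)
  expect_error(load_config(path), "viscocity")
  writeLines("fluids:\n  viscosity: 0.001", path)
  expect_error(load_config(path), "fluids")
})

test_that("config save/load round trip is the identity", {
  path <- withr::local_tempfile(fileext = ".yaml")
  config <- default_run_config()
  config$magnet$h0_kA_m <- 32
  save_config(config, path)
  expect_equal(unclass(load_config(path)), unclass(config))
})

test_that("composition command writes the reference table", {
  out <- withr::local_tempdir()
  files <- run_pipeline("composition", out_dir = out, seed = 1)
  tab <- read_output_table(file.path(out, "composition.csv"))
  expect_equal(round(tab$gamma, 3), 0.698)
  expect_equal(tab$alpha_prime, 14.9, tolerance = 1e-3)
  header <- readLines(file.path(out, "composition.csv"), n = 4)
  expect_true(all(startsWith(header, "#")))
  expect_match(header[3], "seed: 1")
})

test_that("force-curve output is byte-identical across re-runs", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_pipeline("force-curve", out_dir = out1, seed = 4)
  run_pipeline("force-curve", out_dir = out2, seed = 4)
  expect_identical(readLines(file.path(out1, "force_curve.csv")),
                   readLines(file.path(out2, "force_curve.csv")))
  tab <- read_output_table(file.path(out1, "force_curve.csv"))
  expect_true(all(diff(tab$force_N) > 0))
})

test_that("simulate command records a passed outcome without a magnet", {
  out <- withr::local_tempdir()
  run_pipeline("simulate", config = fast_sim_config(0), out_dir = out,
               seed = 1)
  s <- read_output_table(file.path(out, "summary.csv"))
  expect_identical(s$outcome, "passed")
  traj <- read_output_table(file.path(out, "trajectory.csv"))
  expect_true(all(diff(traj$t_s) > 0))
  expect_true(all(c("t_s", "x_m", "y_m", "vx_m_s", "vy_m_s", "contact",
                    "Fmag_x_N", "Fmag_y_N", "Fdrag_x_N", "Flift_y_N")
                  %in% names(traj)))
})

test_that("synth and analyze-track commands chain through files", {
  out <- withr::local_tempdir()
  files <- run_pipeline("synth", out_dir = out, seed = 2)
  expect_true(all(file.exists(files)))
  psd <- read_output_table(file.path(out, "psd.csv"))
  expect_equal(nrow(psd), 10000)
  expect_lt(abs(mean(psd$diameter_nm) - 248), 3)

  expect_error(run_pipeline("analyze-track", out_dir = out,
                            track_file = file.path(out, "absent.csv")),
               "track_file")
  # build a track table and analyze it
  t <- seq(0, 0.3, by = 1e-3)
  utils::write.csv(data.frame(t = t, x = 0.3 * t, y = 0.003),
                   file.path(out, "track.csv"), row.names = FALSE)
  run_pipeline("analyze-track", out_dir = out,
               track_file = file.path(out, "track.csv"))
  vp <- read_output_table(file.path(out, "velocity_profile.csv"))
  expect_lt(max(abs(vp$vx - 0.3)), 1e-6)
})
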