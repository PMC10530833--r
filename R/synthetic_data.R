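# Generators emulating the experimental inputs: particle-size distributions,
# bead-diameter populations, and noisy video tracks of bead motion. All
# generators are pure functions of their parameters and seed.

#' Sample a particle-size distribution
#'
#' Truncated-Gaussian caliper diameters (truncation at zero). The reference
#' magnetite batch is described by a Gaussian with median 248 nm and
#' dispersion 57 nm.
#'
#' @param n Number of particles, >= 1.
#' @param median Distribution median (nm), > 0.
#' @param dispersion Distribution standard deviation (nm), >= 0; 0 returns
#'   the median for every particle.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @return Numeric vector of diameters (nm).
#' @examples
#' d <- sample_psd(1000, seed = 7)
#' mean(d)
#' @export
sample_psd <- function(n, median = 248, dispersion = 57, seed = 1L) {
  check_number(n, "n", positive = TRUE)
  check_number(median, "median", positive = TRUE)
  check_number(dispersion, "dispersion", nonnegative = TRUE)
  n <- as.integer(n)
  if (dispersion == 0) return(rep(median, n))
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(n, mean = median, sd = dispersion)
      out <- c(out, draw[draw > 0])
    }
    out[seq_len(n)]
  })
}

#' Weight-average diameter of a particle sample
#'
#' \eqn{D_w = \sum d^4 / \sum d^3}: the volume(weight)-weighted mean caliper
#' diameter, always at least the number average.
#'
#' @param diameters Positive particle diameters.
#' @return Weight-average diameter in the input units.
#' @examples
#' weight_average_diameter(sample_psd(1e4, seed = 1))
#' @export
weight_average_diameter <- function(diameters) {
  if (length(diameters) == 0)
    stop_domain("'diameters' must be nonempty")
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop_domain("'diameters' must be positive and finite")
  sum(diameters^4) / sum(diameters^3)
}

#' Generate a bead-diameter population
#'
#' Gaussian bead diameters truncated at three standard deviations around the
#' mean. The reference beads have mean diameter 2.37 mm with a per-bead
#' standard deviation of 0.12 mm.
#'
#' @param n Number of beads, >= 1.
#' @param mean_diameter Mean diameter (mm), > 0.
#' @param sd Standard deviation (mm), >= 0.
#' @param seed Integer seed.
#' @return Numeric vector of diameters (mm).
#' @examples
#' generate_bead_population(100, seed = 3)
#' @export
generate_bead_population <- function(n, mean_diameter = 2.37, sd = 0.12,
                                     seed = 1L) {
  check_number(n, "n", positive = TRUE)
  check_number(mean_diameter, "mean_diameter", positive = TRUE)
  check_number(sd, "sd", nonnegative = TRUE)
  n <- as.integer(n)
  if (sd == 0) return(rep(mean_diameter, n))
  lo <- mean_diameter - 3 * sd
  hi <- mean_diameter + 3 * sd
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(n, mean = mean_diameter, sd = sd)
      out <- c(out, draw[draw >= lo & draw <= hi & draw > 0])
    }
    out[seq_len(n)]
  })
}

#' Synthesize a noisy observed track from a trajectory
#'
#' Emulates the video-tracking observation process: the true trajectory is
#' resampled at the camera frame rate (linear interpolation) and Gaussian
#' position noise is added independently to each coordinate.
#'
#' @param traj Data frame with columns `t`, `x`, `y` (a `bead_trajectory`
#'   works directly).
#' @param position_sd Position noise standard deviation (m), >= 0.
#' @param frame_rate Camera frame rate (1/s), > 0; default 1000 fps.
#' @param seed Integer seed.
#' @return Data frame with columns `t`, `x`, `y` at frame instants.
#' @export
synthetic_track <- function(traj, position_sd = 1e-5, frame_rate = 1000,
                            seed = 1L) {
  check_number(position_sd, "position_sd", nonnegative = TRUE)
  check_number(frame_rate, "frame_rate", positive = TRUE)
  t_range <- range(traj$t)
  frames <- seq(t_range[1], t_range[2], by = 1 / frame_rate)
  if (length(frames) < 2)
    stop_domain("trajectory must span at least two frames at this frame rate")
  x <- stats::approx(traj$t, traj$x, xout = frames)$y
  y <- stats::approx(traj$t, traj$y, xout = frames)$y
  if (position_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(2 * length(frames),
                                          sd = position_sd))
    x <- x + noise[seq_along(frames)]
    y <- y + noise[length(frames) + seq_along(frames)]
  }
  data.frame(t = frames, x = x, y = y)
}
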