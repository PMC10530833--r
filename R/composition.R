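# Gel/filler composition arithmetic: swelling ratios, magnetite weight and
# volume fractions, and susceptibility from a reference-composite calibration.
#
# All public operations take and return fractions in [0, 1]; percent values
# appear only in formatted output.

#' Equilibrium swelling ratio of a gel
#'
#' Mass of absorbed water per unit mass of dry gel,
#' \eqn{\alpha = (m - m_0)/m_0}, from a gravimetric swelling measurement.
#'
#' @param swollen_mass Mass of the equilibrium-swollen gel (g).
#' @param dry_mass Mass of the dried residue (g); must be positive and not
#'   exceed `swollen_mass`.
#' @return Dimensionless swelling ratio (>= 0).
#' @examples
#' swelling_ratio(5.5, 1.0)   # ferrogel beads
#' swelling_ratio(15.4, 1.0)  # blank hydrogel
#' @export
swelling_ratio <- function(swollen_mass, dry_mass) {
  check_number(dry_mass, "dry_mass", positive = TRUE)
  check_number(swollen_mass, "swollen_mass", positive = TRUE)
  if (swollen_mass < dry_mass)
    stop_domain("'swollen_mass' must be >= 'dry_mass': swelling cannot be negative")
  (swollen_mass - dry_mass) / dry_mass
}

#' Weight fraction of magnetite in the dried ferrogel
#'
#' From the integral thermogravimetric weight losses of the blank hydrogel
#' and the magnetite-filled ferrogel: \eqn{\gamma = 1 - \Delta_{FG}/\Delta_{HG}}.
#' The magnetite filler survives thermal decomposition, so a filled gel loses
#' proportionally less weight.
#'
#' @param loss_hg Integral weight loss of the blank hydrogel (percent, in
#'   (0, 100]).
#' @param loss_fg Integral weight loss of the ferrogel (percent, in
#'   (0, `loss_hg`]).
#' @return Weight fraction of magnetite in the dry gel, in \[0, 1).
#' @examples
#' magnetite_fraction_dry(86.32, 26.07)  # 0.698
#' @export
magnetite_fraction_dry <- function(loss_hg, loss_fg) {
  check_number(loss_hg, "loss_hg", positive = TRUE)
  check_number(loss_fg, "loss_fg", positive = TRUE)
  if (loss_hg > 100 || loss_fg > 100)
    stop_domain("weight losses are percentages and cannot exceed 100")
  if (loss_fg > loss_hg)
    stop_domain("'loss_fg' > 'loss_hg': composition impossible (filler cannot add weight loss)")
  1 - loss_fg / loss_hg
}

#' Swelling ratio of the polymer matrix alone
#'
#' The integral swelling ratio of a filled gel counts the (non-swelling)
#' filler in the dry mass. Excluding the filler,
#' \eqn{\alpha' = \alpha / (1 - \gamma)}.
#'
#' @param alpha Integral swelling ratio of the filled gel (dimensionless).
#' @param gamma Weight fraction of filler in the dry gel, in \[0, 1).
#' @return Matrix swelling ratio \eqn{\alpha' \ge \alpha}.
#' @examples
#' matrix_swelling(4.5, 0.698)  # ~14.9, close to the blank-gel value 14.4
#' @export
matrix_swelling <- function(alpha, gamma) {
  check_number(alpha, "alpha", nonnegative = TRUE)
  check_fraction(gamma, "gamma")
  if (gamma >= 1)
    stop_domain("'gamma' must be < 1: a gel cannot be pure filler")
  alpha / (1 - gamma)
}

#' Weight fraction of magnetite in the swollen bead
#'
#' Dilution of the dry-gel filler fraction by absorbed water:
#' \eqn{\omega = \gamma / (1 + \alpha)}.
#'
#' @param gamma Weight fraction of filler in the dry gel, in \[0, 1\].
#' @param alpha Integral swelling ratio (>= 0).
#' @return Weight fraction of filler in the swollen bead, `<= gamma`.
#' @examples
#' magnetite_fraction_swollen(0.698, 4.5)  # ~0.127 (12.7 wt%)
#' @export
magnetite_fraction_swollen <- function(gamma, alpha) {
  check_fraction(gamma, "gamma")
  check_number(alpha, "alpha", nonnegative = TRUE)
  gamma / (1 + alpha)
}

#' Volume fraction of filler from its weight fraction
#'
#' Dilute approximation \eqn{\phi = \omega \rho_{gel} / \rho_{particle}}:
#' the swollen bead density multiplies the weight fraction into filler mass
#' per unit bead volume, which the particle density converts to a volume
#' fraction. Cross terms of order \eqn{\phi^2} are neglected.
#'
#' @param omega Weight fraction of filler in the swollen bead, in \[0, 1\].
#' @param rho_gel Density of the swollen bead (kg/m^3).
#' @param rho_particle Density of the filler particles (kg/m^3); bulk
#'   magnetite is 5180 kg/m^3.
#' @return Volume fraction of filler, in \[0, 1\].
#' @examples
#' volume_fraction_from_weight(0.126, 1110, 5180)
#' @export
volume_fraction_from_weight <- function(omega, rho_gel, rho_particle) {
  check_fraction(omega, "omega")
  check_number(rho_gel, "rho_gel", positive = TRUE)
  check_number(rho_particle, "rho_particle", positive = TRUE)
  omega * rho_gel / rho_particle
}

#' Bead susceptibility from a reference-composite calibration
#'
#' Linear scaling of the measured susceptibility of a reference composite to
#' the bead's filler volume fraction:
#' \eqn{\chi = \chi_{ref} \, \phi / \phi_{ref}}.
#'
#' @param phi Volume fraction of magnetite in the bead, in \[0, 1\].
#' @param chi_ref Volume susceptibility of the reference composite
#'   (SI, dimensionless); default 0.408 for the epoxy/magnetite reference.
#' @param phi_ref Volume fraction of magnetite in the reference composite,
#'   as a fraction; default 0.0957.
#' @return Volume magnetic susceptibility (SI, dimensionless).
#' @examples
#' susceptibility_from_calibration(0.027)
#' @export
susceptibility_from_calibration <- function(phi, chi_ref = 0.408,
                                            phi_ref = 0.0957) {
  check_fraction(phi, "phi")
  check_number(chi_ref, "chi_ref", positive = TRUE)
  check_number(phi_ref, "phi_ref", positive = TRUE)
  chi_ref * phi / phi_ref
}

#' Full composition chain for a ferrogel bead
#'
#' Chains the composition operations: integral swelling ratio, dry-gel
#' filler weight fraction from thermogravimetric losses, matrix swelling
#' ratio, swollen-bead filler weight and volume fractions, and the
#' calibration-derived susceptibility.
#'
#' The chain-derived susceptibility is reported as `chi_chain`; because the
#' volume fraction entering the calibration is not measured directly, an
#' independently measured bead susceptibility can be supplied as
#' `chi_override` and is then carried in `chi` (otherwise `chi = chi_chain`).
#'
#' @param alpha Integral swelling ratio of the ferrogel. Alternatively give
#'   `swollen_mass` and `dry_mass`.
#' @param loss_hg,loss_fg Integral thermogravimetric weight losses (percent)
#'   of the blank hydrogel and the ferrogel.
#' @param swollen_mass,dry_mass Optional swelling measurement (g) used to
#'   compute `alpha` when `alpha` is missing.
#' @param rho_gel Swollen bead density (kg/m^3).
#' @param rho_particle Filler particle density (kg/m^3).
#' @param chi_ref,phi_ref Reference-composite calibration (susceptibility
#'   and volume fraction, fraction units).
#' @param chi_override Optional measured bead susceptibility that replaces
#'   the chain-derived value in `chi`.
#' @return An object of class `gel_composition`: a list with `alpha`,
#'   `gamma`, `alpha_prime`, `omega`, `phi`, `chi_chain` and `chi`.
#' @examples
#' gel_composition(alpha = 4.5, loss_hg = 86.32, loss_fg = 26.07,
#'                 chi_override = 0.13)
#' @export
gel_composition <- function(alpha = NULL, loss_hg, loss_fg,
                            swollen_mass = NULL, dry_mass = NULL,
                            rho_gel = 1110, rho_particle = 5180,
                            chi_ref = 0.408, phi_ref = 0.0957,
                            chi_override = NULL) {
  if (is.null(alpha)) {
    if (is.null(swollen_mass) || is.null(dry_mass))
      stop_domain("give either 'alpha' or both 'swollen_mass' and 'dry_mass'")
    alpha <- swelling_ratio(swollen_mass, dry_mass)
  }
  gamma <- magnetite_fraction_dry(loss_hg, loss_fg)
  alpha_prime <- matrix_swelling(alpha, gamma)
  omega <- magnetite_fraction_swollen(gamma, alpha)
  phi <- volume_fraction_from_weight(omega, rho_gel, rho_particle)
  chi_chain <- susceptibility_from_calibration(phi, chi_ref, phi_ref)
  if (!is.null(chi_override)) check_number(chi_override, "chi_override",
                                           nonnegative = TRUE)
  out <- list(alpha = alpha, gamma = gamma, alpha_prime = alpha_prime,
              omega = omega, phi = phi, chi_chain = chi_chain,
              chi = if (is.null(chi_override)) chi_chain else chi_override,
              rho_gel = rho_gel, rho_particle = rho_particle)
  class(out) <- "gel_composition"
  out
}

#' @export
print.gel_composition <- function(x, digits = 4, ...) {
  cat("Ferrogel bead composition\n")
  cat(sprintf("  integral swelling ratio (alpha):        %.*g\n", digits, x$alpha))
  cat(sprintf("  magnetite in dry gel (gamma):           %.*g\n", digits, x$gamma))
  cat(sprintf("  matrix swelling ratio (alpha'):         %.*g\n", digits, x$alpha_prime))
  cat(sprintf("  magnetite in swollen bead (omega):      %.*g%%\n", digits, 100 * x$omega))
  cat(sprintf("  magnetite volume fraction (phi):        %.*g%%\n", digits, 100 * x$phi))
  cat(sprintf("  susceptibility, composition chain:      %.*g\n", digits, x$chi_chain))
  if (!identical(x$chi, x$chi_chain))
    cat(sprintf("  susceptibility in use (override):       %.*g\n", digits, x$chi))
  invisible(x)
}
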