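#' Rigid 3-site water model description
#'
#' Bundles the geometric and nonbonded parameters of a rigid 3-site water
#' model together with its bulk reference quantities: the reference number
#' density `rho0` used to normalise densities and entropies, and the bulk
#' per-water water-water interaction energy `eww_ref` subtracted when
#' referencing voxel energies to the neat liquid.
#'
#' Defaults correspond to TIP3P-like water: O-H bond 0.9572 Angstrom,
#' equilibrium H-O-H angle 104.5 degrees, charges -0.834 e (O) / +0.417 e (H),
#' Lennard-Jones sigma 3.15061 Angstrom and epsilon 0.1521 kcal/mol on the
#' oxygen only, rho0 = 0.0334 molecules/Angstrom^3 and
#' eww_ref = -9.533 kcal/mol.
#'
#' @param name model name.
#' @param rho0 bulk number density in molecules/Angstrom^3.
#' @param oh_length rigid O-H bond length in Angstrom.
#' @param hoh_angle_eq equilibrium H-O-H angle in degrees.
#' @param eww_ref bulk per-water water-water interaction energy in kcal/mol.
#' @param q_o,q_h partial charges of O and H in elementary charges.
#' @param sigma_o,epsilon_o,sigma_h,epsilon_h Lennard-Jones parameters
#'   (sigma in Angstrom, epsilon in kcal/mol).
#'
#' @return An object of class `water_model`.
#' @examples
#' wm <- water_model()
#' wm$hoh_angle_eq
#' @export
water_model <- function(name = "TIP3P",
                        rho0 = 0.0334,
                        oh_length = 0.9572,
                        hoh_angle_eq = 104.5,
                        eww_ref = -9.533,
                        q_o = -0.834, q_h = 0.417,
                        sigma_o = 3.15061, epsilon_o = 0.1521,
                        sigma_h = 0, epsilon_h = 0) {
  stopifnot(rho0 > 0, oh_length > 0,
            hoh_angle_eq > 0, hoh_angle_eq < 180)
  structure(list(name = name, rho0 = rho0, oh_length = oh_length,
                 hoh_angle_eq = hoh_angle_eq, eww_ref = eww_ref,
                 q_o = q_o, q_h = q_h,
                 sigma_o = sigma_o, epsilon_o = epsilon_o,
                 sigma_h = sigma_h, epsilon_h = epsilon_h),
            class = "water_model")
}

#' @export
print.water_model <- function(x, ...) {
  cat("Rigid 3-site water model:", x$name, "\n")
  cat(sprintf("  O-H %.4f A, H-O-H %.2f deg\n", x$oh_length, x$hoh_angle_eq))
  cat(sprintf("  rho0 %.4f / A^3, Eww(ref) %.3f kcal/mol\n",
              x$rho0, x$eww_ref))
  invisible(x)
}

#' Physical constants and settings for the GIST thermodynamics
#'
#' Collects the constants entering the per-voxel energy and entropy
#' expressions: the temperature, the ideal gas constant in kcal/(mol K),
#' Euler's constant (the asymptotic bias correction of the nearest-neighbour
#' entropy estimator), the Coulomb constant in kcal Angstrom/(mol e^2), and
#' the bulk references `rho0` and `eww_ref` taken from the water model.
#'
#' @param temperature simulation temperature in K (default 300).
#' @param model a [water_model()]; supplies `rho0` and `eww_ref`.
#' @param eww_ref_mode how the bulk water-water reference is subtracted from
#'   the per-observation water-water energy, which carries a global 1/2
#'   double-counting factor: `"half"` (default) subtracts `eww_ref/2` per
#'   observation so that bulk voxels read ~0; `"full"` subtracts the whole
#'   `eww_ref`.
#' @return An object of class `gist_params`.
#' @examples
#' p <- gist_params()
#' p$gas_constant
#' @export
gist_params <- function(temperature = 300,
                        model = water_model(),
                        eww_ref_mode = c("half", "full")) {
  stopifnot(temperature > 0, inherits(model, "water_model"))
  eww_ref_mode <- match.arg(eww_ref_mode)
  structure(list(temperature = temperature,
                 gas_constant = 1.987204e-3,      # kcal/(mol K)
                 euler_gamma = 0.5772156649015329,
                 coulomb_constant = 332.0636,     # kcal A / (mol e^2)
                 rho0 = model$rho0,
                 eww_ref = model$eww_ref,
                 eww_ref_mode = eww_ref_mode,
                 model = model),
            class = "gist_params")
}

#' @export
print.gist_params <- function(x, ...) {
  cat(sprintf("GIST parameters: T = %g K, rho0 = %.4f / A^3,",
              x$temperature, x$rho0))
  cat(sprintf(" Eww(ref) = %.3f kcal/mol (%s subtraction)\n",
              x$eww_ref, x$eww_ref_mode))
  invisible(x)
}
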