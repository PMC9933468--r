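#' Suspension parameters for charged nanorods
#'
#' Physical parameters of a rod suspension (cellulose nanocrystals being
#' the motivating system): rod length and width in nm, line valency
#' density \eqn{\xi = Z/a} (effective elementary charges per nm of rod)
#' and the Bjerrum length of the solvent.
#'
#' @param a_nm rod length (nm).
#' @param d_nm rod width (nm); only used for effective aspect ratios.
#' @param xi line valency density \eqn{\xi} (1/nm).
#' @param l_B_nm Bjerrum length (nm); 0.71 nm for water at 298 K.
#' @param temperature temperature in K (metadata).
#' @return An object of class \code{"suspension_params"} with the derived
#'   total valency \code{Z}.
#' @export
suspension_params <- function(a_nm, d_nm = NA_real_, xi, l_B_nm = 0.71,
                              temperature = 298) {
  stopifnot(a_nm > 0, xi >= 0, l_B_nm > 0, temperature > 0)
  structure(list(a_nm = a_nm, d_nm = d_nm, xi = xi, l_B_nm = l_B_nm,
                 temperature = temperature, Z = xi * a_nm),
            class = "suspension_params")
}

#' @export
print.suspension_params <- function(x, ...) {
  cat(sprintf("suspension: a = %g nm, xi = %g /nm (Z = %g), l_B = %g nm\n",
              x$a_nm, x$xi, x$Z, x$l_B_nm))
  invisible(x)
}

# counterion number density (1/nm^3) at reduced density rho_star when the
# only screening ions are the rods' dissociated monovalent counterions
.counterion_density <- function(xi, a_nm, rho_star) {
  xi * rho_star / a_nm^2           # Z * rho = (xi a) * (rho* / a^3)
}

#' Reduced screening along an evaporation path
#'
#' During evaporation (densification) of a salt-free suspension the only
#' screening ions are the rods' own dissociated monovalent counterions, of
#' number density \eqn{c = Z\rho = \xi\rho^*/a^2}. With
#' \eqn{\kappa^2 = 4\pi l_B c} this ties the reduced screening to the
#' reduced density:
#' \deqn{\kappa^* = \sqrt{4\pi\, l_B\, \xi\, \rho^*}.}
#'
#' @param xi line valency density (1/nm).
#' @param a_nm rod length (nm); enters only through the reduced units.
#' @param l_B_nm Bjerrum length (nm).
#' @param rho_star reduced density (may be a vector).
#' @return \eqn{\kappa^*} (dimensionless), same length as
#'   \code{rho_star}.
#' @export
evaporation_kappa <- function(xi, a_nm, l_B_nm = 0.71, rho_star) {
  stopifnot(xi >= 0, a_nm > 0, l_B_nm > 0, all(rho_star > 0))
  sqrt(4 * pi * l_B_nm * xi * rho_star)
}

#' Inverse of the evaporation relation
#'
#' @param kappa_star reduced inverse screening length.
#' @inheritParams evaporation_kappa
#' @return The reduced density \eqn{\rho^* = \kappa^{*2}/(4\pi l_B \xi)}.
#' @export
evaporation_rho <- function(xi, a_nm, l_B_nm = 0.71, kappa_star) {
  stopifnot(xi > 0, l_B_nm > 0, all(kappa_star >= 0))
  kappa_star^2 / (4 * pi * l_B_nm * xi)
}

#' pH of a proton-counterion suspension state
#'
#' When the dissociated counterions are protons (e.g. sulfate half-ester
#' groups titrated to their acid form), the counterion molarity sets the
#' pH directly: \eqn{pH = -\log_{10} c_{mol/L}}.
#'
#' @inheritParams evaporation_kappa
#' @return pH values, same length as \code{rho_star}.
#' @examples
#' ph_from_state(xi = 2, a_nm = 150, rho_star = 17) # about 2.6
#' @export
ph_from_state <- function(xi, a_nm, rho_star) {
  stopifnot(xi > 0, a_nm > 0, all(rho_star > 0))
  c_nm3 <- .counterion_density(xi, a_nm, rho_star)
  molar <- c_nm3 * 1e24 / 6.02214076e23   # nm^-3 -> mol/L
  -log10(molar)
}

#' Effective aspect ratio of electrostatically swollen rods
#'
#' Models the repulsion range as an added layer of one screening length on
#' every surface: \eqn{a' = a + 2\kappa^{-1}}, \eqn{d' = d +
#' 2\kappa^{-1}}, so the effective aspect ratio is \eqn{a'/d'}.
#'
#' @param a_nm rod length (nm).
#' @param d_nm rod width (nm).
#' @param debye_nm Debye screening length \eqn{\kappa^{-1}} (nm).
#' @return The effective aspect ratio \eqn{(a + 2\kappa^{-1})/(d +
#'   2\kappa^{-1})}.
#' @examples
#' effective_aspect_ratio(115, 7, 10) # = 5
#' @export
effective_aspect_ratio <- function(a_nm, d_nm, debye_nm) {
  stopifnot(a_nm > 0, d_nm > 0, debye_nm >= 0)
  (a_nm + 2 * debye_nm) / (d_nm + 2 * debye_nm)
}

#' Line valency density from material properties
#'
#' Estimates \eqn{\xi = Z/a} for rectangular rods from either a surface
#' density of ionisable sites (charges per nm^2 on the four lateral
#' faces) or a per-mass site density (mol of sites per gram, with the
#' material's mass density).
#'
#' @param dims_nm rod dimensions \code{c(width, depth, length)} in nm.
#' @param site_density site density: e/nm^2 for \code{basis =
#'   "per_area"}, mol/g for \code{basis = "per_mass"}.
#' @param basis \code{"per_area"} or \code{"per_mass"}.
#' @param mass_density_kg_m3 material mass density (required for
#'   \code{"per_mass"}).
#' @return \eqn{\xi} in 1/nm, with the total valency \code{Z} as an
#'   attribute.
#' @examples
#' line_valency_from_material(c(7, 7, 115), 0.115, "per_area")
#' line_valency_from_material(c(5, 5, 150), 0.23e-3, "per_mass", 1600)
#' @export
line_valency_from_material <- function(dims_nm, site_density,
                                       basis = c("per_area", "per_mass"),
                                       mass_density_kg_m3 = NULL) {
  basis <- match.arg(basis)
  stopifnot(length(dims_nm) == 3, all(dims_nm > 0), site_density >= 0)
  a <- dims_nm[3]
  if (basis == "per_area") {
    lateral <- 2 * (dims_nm[1] + dims_nm[2]) * a   # four lateral faces
    Z <- site_density * lateral
  } else {
    if (is.null(mass_density_kg_m3))
      stop("mass_density_kg_m3 is required for the per-mass basis")
    vol_nm3 <- prod(dims_nm)
    mass_g <- mass_density_kg_m3 * 1e3 * vol_nm3 * 1e-27  # kg/m^3 -> g/nm^3
    Z <- site_density * mass_g * 6.02214076e23
  }
  structure(Z / a, Z = Z)
}

#' Valency for which a reduced barrier equals the thermal energy
#'
#' Converts a reduced energy barrier \eqn{\Delta\tilde u} (in units
#' \eqn{a/(Z^2 l_B)}, as produced by the lattice scans) into the line
#' valency density at which the physical barrier equals \eqn{k_B T}:
#' \eqn{Z^2 (l_B/a) \Delta\tilde u = 1}, i.e.
#' \eqn{Z = \sqrt{a/(l_B \Delta\tilde u)}}, \eqn{\xi = Z/a}.
#'
#' @param delta_u_reduced reduced barrier height (> 0).
#' @param a_nm rod length (nm).
#' @param l_B_nm Bjerrum length (nm).
#' @return \eqn{\xi} in 1/nm with \code{Z} as an attribute.
#' @export
barrier_to_line_charge <- function(delta_u_reduced, a_nm, l_B_nm = 0.71) {
  stopifnot(delta_u_reduced > 0, a_nm > 0, l_B_nm > 0)
  Z <- sqrt(a_nm / (l_B_nm * delta_u_reduced))
  structure(Z / a_nm, Z = Z)
}

#' Electrostatic coupling parameters
#'
#' Dimensionless ratios of a characteristic electrostatic energy to
#' \eqn{k_B T}, \eqn{\Lambda = Z^2 l_B / \ell}, for the three natural
#' choices of the length \eqn{\ell}: the screening length
#' \eqn{\kappa^{-1}}, the mean inter-rod spacing \eqn{\rho^{-1/3}}, and
#' the rod length \eqn{a}. All three scale as \eqn{\xi^2 a} at fixed
#' \eqn{(\rho^*, \kappa^*)}.
#'
#' @param xi line valency density (1/nm).
#' @param a_nm rod length (nm).
#' @param l_B_nm Bjerrum length (nm).
#' @param rho_star,kappa_star the reduced state point.
#' @return A data frame with \code{lambda_screen}, \code{lambda_spacing}
#'   and \code{lambda_rod}.
#' @export
coupling_parameters <- function(xi, a_nm, l_B_nm = 0.71, rho_star,
                                kappa_star) {
  stopifnot(xi >= 0, a_nm > 0, all(rho_star > 0), all(kappa_star > 0))
  Z <- xi * a_nm
  base <- Z^2 * l_B_nm / a_nm     # ell = a
  data.frame(lambda_screen = base * kappa_star,
             lambda_spacing = base * rho_star^(1 / 3),
             lambda_rod = base)
}

#' Evaporation curve of a salt-free rod suspension
#'
#' Tabulates the path a concentrating suspension follows in the
#' \eqn{(\rho^*, \kappa^*)} plane under counterion-only screening,
#' together with the pH (proton counterions) and the three coupling
#' parameters.
#'
#' @param xi line valency density (1/nm).
#' @param a_nm rod length (nm).
#' @param l_B_nm Bjerrum length (nm).
#' @param rho_star_range range of reduced densities.
#' @param n number of points.
#' @return A data frame (class \code{"evaporation_curve"}) with columns
#'   \code{rho_star}, \code{kappa_star}, \code{pH},
#'   \code{lambda_screen}, \code{lambda_spacing}, \code{lambda_rod}.
#' @export
evaporation_curve <- function(xi, a_nm, l_B_nm = 0.71,
                              rho_star_range = c(1, 30), n = 60) {
  stopifnot(length(rho_star_range) == 2, all(rho_star_range > 0), n >= 2)
  rho <- seq(rho_star_range[1], rho_star_range[2], length.out = n)
  ks <- evaporation_kappa(xi, a_nm, l_B_nm, rho)
  out <- data.frame(rho_star = rho, kappa_star = ks,
                    pH = ph_from_state(xi, a_nm, rho),
                    coupling_parameters(xi, a_nm, l_B_nm, rho, ks))
  class(out) <- c("evaporation_curve", "data.frame")
  attr(out, "xi") <- xi
  attr(out, "a_nm") <- a_nm
  attr(out, "l_B_nm") <- l_B_nm
  out
}

#' @export
plot.evaporation_curve <- function(x, ...) {
  graphics::plot(x$rho_star, x$kappa_star, type = "l",
                 xlab = expression(rho^"*"), ylab = expression(kappa^"*"),
                 ...)
  invisible(x)
}
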