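#' Interaction parameters for segmented charged rods
#'
#' Defines the far-field anisotropic screened-Coulomb (Yukawa) interaction
#' model for rigid linear rods of length \eqn{a} carrying \eqn{Z} effective
#' elementary charges, discretised into \eqn{M} collinear segments of
#' length \eqn{a/M}, each with charge \eqn{Z/M}.
#'
#' All lengths are reduced by the rod length (\eqn{a = 1} internally); the
#' inverse Debye screening length enters as \eqn{\kappa^* = \kappa a}. The
#' reduced energy between two segments \eqn{i} and \eqn{j} is
#' \deqn{\beta u_{ij} = \left(\frac{Z}{M}\right)^2 \lambda^*
#'   \, S(x_i)\, S(x_j) \, \frac{e^{-\kappa^* r_{ij}}}{r_{ij}},
#'   \qquad S(x) = \frac{\sinh x}{x},
#'   \quad x_n = \frac{\kappa^*}{2M} (\hat v_n \cdot \hat r_{ij}),}
#' the large-separation interaction of two uniformly charged line segments
#' in a screened medium. \eqn{\lambda^* = \lambda/a} is the energy length
#' scale (the Bjerrum length for energies in units of \eqn{k_B T}). With
#' the defaults \code{Z = 1}, \code{lambda_ref = 1} all energies are in
#' the reduced unit \eqn{\beta u\, a / (Z^2 l_B)}.
#'
#' @param kappa_star reduced inverse screening length \eqn{\kappa a > 0}.
#' @param M number of segments per rod (positive integer).
#' @param Z total valency (effective elementary charges) per rod.
#' @param lambda_ref energy length scale \eqn{\lambda} in units of the rod
#'   length; the Bjerrum length for energies in \eqn{k_B T}.
#' @param n_trunc truncation integer of the cutoff rule (see
#'   [truncation_radii()]).
#' @param a_nm physical rod length in nm, kept as metadata for mapping to
#'   suspension conditions; not used by the reduced-unit energies.
#'
#' @return An object of class \code{"potential_params"}.
#' @seealso [segment_pair_energy()], [rod_pair_energy()],
#'   [truncation_radii()]
#' @examples
#' p <- potential_params(kappa_star = 20)
#' rod_pair_energy(c(0, 0, 0), c(0, 0, 1), c(0.34, 0, 0), c(0, 0, 1), p)
#' @export
potential_params <- function(kappa_star, M = 15L, Z = 1, lambda_ref = 1,
                             n_trunc = 10L, a_nm = NA_real_) {
  stopifnot(is.numeric(kappa_star), length(kappa_star) == 1, kappa_star > 0)
  M <- as.integer(M)
  n_trunc <- as.integer(n_trunc)
  stopifnot(M >= 1L, n_trunc >= 1L, Z > 0, lambda_ref > 0)
  structure(
    list(kappa_star = kappa_star, M = M, Z = Z, lambda_ref = lambda_ref,
         n_trunc = n_trunc, a_nm = a_nm),
    class = "potential_params")
}

#' @export
print.potential_params <- function(x, ...) {
  cat("Segmented-rod screened-Coulomb potential\n")
  cat(sprintf("  kappa* = %g, M = %d segments (segment length 1/M = %.4g)\n",
              x$kappa_star, x$M, 1 / x$M))
  cat(sprintf("  Z = %g, lambda* = %g, n_trunc = %d\n",
              x$Z, x$lambda_ref, x$n_trunc))
  if (!is.na(x$a_nm)) cat(sprintf("  physical rod length a = %g nm\n", x$a_nm))
  invisible(x)
}

# energy prefactor Z^2 lambda* carried by all pair energies
.u_scale <- function(params) params$Z^2 * params$lambda_ref

.check_unit <- function(v, name) {
  if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
    stop(name, " must be a unit vector", call. = FALSE)
  invisible(TRUE)
}

#' Segment-segment interaction energy
#'
#' Far-field screened-Coulomb energy between two charged rod segments
#' (see [potential_params()] for the closed form). Purely repulsive,
#' invariant under exchanging the segments (with \eqn{r \to -r}) and under
#' flipping either rod axis (head--tail symmetry).
#'
#' @param r_ij centre-to-centre separation vector between the segments, in
#'   reduced (rod-length) units.
#' @param v_i,v_j orientation unit vectors of the two parent rods.
#' @param params a [potential_params()] object.
#' @return Reduced energy (units \eqn{Z^2 \lambda^*/a}; \eqn{k_B T} when
#'   \code{lambda_ref} is the reduced Bjerrum length).
#' @export
segment_pair_energy <- function(r_ij, v_i, v_j, params) {
  stopifnot(inherits(params, "potential_params"), length(r_ij) == 3)
  if (sum(r_ij^2) == 0) stop("segment separation must be positive")
  .check_unit(v_i, "v_i")
  .check_unit(v_j, "v_j")
  .u_scale(params) *
    cpp_segment_energy(as.numeric(r_ij), as.numeric(v_i), as.numeric(v_j),
                       params$kappa_star, params$M)
}

#' Rod-rod interaction energy
#'
#' Sums [segment_pair_energy()] over all \eqn{M \times M} segment pairs of
#' two rods. Segment centres sit at offsets \eqn{((k - (M+1)/2)/M)\,\hat v}
#' for \eqn{k = 1..M}: equidistant with spacing \eqn{1/M}, symmetric about
#' the rod centre. Rod self-energies are never included.
#'
#' @param pos_p,pos_q rod centre positions (reduced units).
#' @param v_p,v_q rod orientation unit vectors.
#' @param params a [potential_params()] object.
#' @return Reduced energy (same units as [segment_pair_energy()]).
#' @export
rod_pair_energy <- function(pos_p, v_p, pos_q, v_q, params) {
  stopifnot(inherits(params, "potential_params"))
  if (all(pos_p == pos_q)) stop("coincident rods")
  .check_unit(v_p, "v_p")
  .check_unit(v_q, "v_q")
  .u_scale(params) *
    cpp_rod_pair_energy(as.numeric(pos_p), as.numeric(v_p),
                        as.numeric(pos_q), as.numeric(v_q),
                        params$kappa_star, params$M)
}

#' Interaction truncation radii
#'
#' Segment-segment interactions are truncated at the reduced distance
#' \eqn{n_{trunc}/\kappa^* + 1.5\,(\rho^*)^{-1/3}} and rod-rod (centre to
#' centre) interactions at 1 plus that distance. The two terms keep enough
#' neighbours in both the long- and the short-screening-length regime, and
#' the rod cutoff defines the minimal cluster size for lattice sums.
#'
#' @param params a [potential_params()] object.
#' @param rho_star reduced number density \eqn{\rho a^3 > 0}.
#' @return A list with elements \code{segment_cutoff} and
#'   \code{rod_cutoff} (reduced lengths).
#' @export
truncation_radii <- function(params, rho_star) {
  stopifnot(inherits(params, "potential_params"), rho_star > 0)
  seg <- params$n_trunc / params$kappa_star + 1.5 * rho_star^(-1 / 3)
  list(segment_cutoff = seg, rod_cutoff = 1 + seg)
}
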