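#' Crystal lattice specification
#'
#' Stacked hexagonal (or square-based) layers of rods in the xy-plane,
#' repeated along z. Hexagonal layers are triangular lattices with
#' nearest-neighbour spacing \code{l_xy_star}; the layer spacing follows
#' from the fixed reduced density,
#' \deqn{l_z^* = \frac{2}{\sqrt3\, \rho^* \, l_{xy}^{*2}}}
#' (a hexagonal layer occupies area \eqn{(\sqrt3/2) l_{xy}^2} per rod), or
#' \eqn{l_z^* = 1/(\rho^* l_{xy}^{*2})} for the square-based variants.
#'
#' Successive layers repeat in registry (\code{"AAA"}), alternate between
#' the two close-packing interstitial registries (\code{"ABA"}, hcp), or
#' cycle through three registries (\code{"ABC"}, fcc-like).
#' \code{"cubicAAA"}/\code{"cubicABA"} are square-based stacks (simple /
#' body-centred), kept as a higher-energy cross-check.
#'
#' The in-plane basis is oriented so that nearest-neighbour directions lie
#' at \eqn{30^\circ + k\,60^\circ} from the x-axis: the azimuth origin
#' (\eqn{\psi = 0}) points along a second-neighbour lattice direction.
#' This ties the twist angles \eqn{\Theta_1 \in \{0, 60, 120, 180\}} to
#' the lattice in the geometry where tilted rods run "between" their
#' nearest neighbours, with their closest on-axis contacts at
#' second-neighbour positions.
#'
#' @param stacking one of \code{"AAA"}, \code{"ABA"}, \code{"ABC"},
#'   \code{"cubicAAA"}, \code{"cubicABA"}.
#' @param l_xy_star in-plane nearest-neighbour spacing (reduced).
#' @param rho_star reduced number density \eqn{\rho a^3}.
#' @param n_stack number of layers kept when building finite clusters;
#'   \code{NULL} (default) sizes the cluster from the interaction cutoff.
#' @return An object of class \code{"lattice_spec"} with the derived
#'   \code{l_z_star} and stacking period.
#' @examples
#' lattice_spec("ABC", l_xy_star = 1 / 3, rho_star = 10)
#' @export
lattice_spec <- function(stacking = c("AAA", "ABA", "ABC",
                                      "cubicAAA", "cubicABA"),
                         l_xy_star, rho_star, n_stack = NULL) {
  stacking <- match.arg(stacking)
  stopifnot(l_xy_star > 0, rho_star > 0)
  hex <- stacking %in% c("AAA", "ABA", "ABC")
  l_z <- if (hex) 2 / (sqrt(3) * rho_star * l_xy_star^2)
         else 1 / (rho_star * l_xy_star^2)
  period <- switch(stacking, AAA = 1L, ABA = 2L, ABC = 3L,
                   cubicAAA = 1L, cubicABA = 2L)
  structure(
    list(stacking = stacking, l_xy_star = l_xy_star, rho_star = rho_star,
         l_z_star = l_z, hexagonal = hex, period = period,
         n_stack = n_stack),
    class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("%s %s lattice: l_xy* = %.4g, l_z* = %.4g, rho* = %g\n",
              if (x$hexagonal) "hexagonal" else "square-based",
              x$stacking, x$l_xy_star, x$l_z_star, x$rho_star))
  invisible(x)
}

#' Heliconical orientation field
#'
#' Rod orientations are uniform within a layer and parametrised per layer
#' \eqn{k} by a polar (tilt) angle \eqn{\phi} and an azimuth
#' \eqn{\psi_k = \Theta_2 + k\,\Theta_1}: \eqn{\Theta_1} is the twist per
#' layer and \eqn{\Theta_2} the start angle of layer 0. \eqn{\Theta_1 =
#' 0} gives a unidirectional (possibly tilted) field, \eqn{\phi = 90}
#' with \eqn{\Theta_1 \neq 0} a cholesteric-like field, and intermediate
#' tilts with \eqn{\Theta_1 \neq 0} a heliconical field with a pitch of
#' \eqn{360/\Theta_1} layers.
#'
#' @param phi tilt (polar) angle in degrees.
#' @param theta1 twist angle per layer, degrees (taken modulo 360).
#' @param theta2 start angle of layer 0, degrees.
#' @return An object of class \code{"orientation_field"}.
#' @export
orientation_field <- function(phi, theta1 = 0, theta2 = 0) {
  stopifnot(is.numeric(phi), is.numeric(theta1), is.numeric(theta2))
  structure(list(phi = phi, theta1 = theta1 %% 360, theta2 = theta2),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("orientation field: phi = %g deg, Theta1 = %g deg, Theta2 = %g deg\n",
              x$phi, x$theta1, x$theta2))
  invisible(x)
}

#' Orientation unit vector of a layer
#'
#' @param k layer index (layer 0 has azimuth \eqn{\Theta_2}).
#' @param field an [orientation_field()].
#' @return Unit vector \eqn{(\sin\phi\cos\psi_k, \sin\phi\sin\psi_k,
#'   \cos\phi)} with \eqn{\psi_k = \Theta_2 + k\,\Theta_1}.
#' @export
layer_orientation <- function(k, field) {
  stopifnot(inherits(field, "orientation_field"))
  phi <- field$phi * pi / 180
  psi <- (field$theta2 + k * field$theta1) * pi / 180
  cbind(sin(phi) * cos(psi), sin(phi) * sin(psi),
        rep(cos(phi), length(psi)))
}

#' Rod configuration
#'
#' The state all engines operate on: rod centre positions, orientation
#' unit vectors and (optionally) a periodic cuboid box.
#'
#' @param positions N x 3 matrix of rod centres (reduced coordinates).
#' @param orientations N x 3 matrix of unit vectors.
#' @param box edge lengths of the cuboid box (length-3 numeric), or
#'   \code{NULL} for a finite (non-periodic) cluster.
#' @param periodic logical; positions are wrapped into the box when TRUE.
#' @param layer optional integer vector of layer indices (metadata).
#' @return An object of class \code{"rod_config"}.
#' @export
rod_configuration <- function(positions, orientations, box = NULL,
                              periodic = !is.null(box), layer = NULL) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (nrow(positions) > 0) {
    stopifnot(ncol(positions) == 3, ncol(orientations) == 3,
              nrow(positions) == nrow(orientations))
    nrm <- sqrt(rowSums(orientations^2))
    if (any(abs(nrm - 1) > 1e-8))
      stop("orientation vectors must be unit length")
  }
  if (periodic) {
    stopifnot(length(box) == 3, all(box > 0))
    if (nrow(positions) > 0)
      positions <- sweep(positions, 2, box, function(x, L) x - L * floor(x / L))
  }
  structure(list(positions = positions, orientations = orientations,
                 box = box, periodic = periodic, layer = layer),
            class = "rod_config")
}

#' @export
print.rod_config <- function(x, ...) {
  cat(sprintf("rod configuration: %d rods%s\n", nrow(x$positions),
              if (x$periodic)
                sprintf(", periodic box %.4g x %.4g x %.4g (rho* = %.4g)",
                        x$box[1], x$box[2], x$box[3],
                        nrow(x$positions) / prod(x$box))
              else " (finite cluster)"))
  invisible(x)
}

# in-plane lattice basis and registry shifts; nearest neighbours at
# 30 + k*60 deg so that psi = 0 is a second-neighbour direction
.lattice_basis <- function(spec) {
  l <- spec$l_xy_star
  if (spec$hexagonal) {
    a1 <- l * c(sqrt(3) / 2, 1 / 2)
    a2 <- l * c(0, 1)
    shifts <- list(c(0, 0), (a1 + a2) / 3, 2 * (a1 + a2) / 3)
  } else {
    a1 <- l * c(1, 0)
    a2 <- l * c(0, 1)
    shifts <- list(c(0, 0), l * c(1 / 2, 1 / 2))
  }
  list(a1 = a1, a2 = a2, shifts = shifts)
}

.registry <- function(k, period) ((k %% period) + period) %% period

#' Build a finite lattice cluster around a central rod
#'
#' Constructs all rods of the crystal within a given centre-to-centre
#' distance (normally the rod cutoff of [truncation_radii()]) of a central
#' rod placed at the origin of layer 0. This spherical cluster is the
#' minimal system for the lattice energy sums.
#'
#' @param spec a [lattice_spec()].
#' @param field an [orientation_field()].
#' @param extent cluster radius (reduced length), typically
#'   \code{truncation_radii(params, rho_star)$rod_cutoff}.
#' @return A [rod_configuration()] (non-periodic) whose first rod is the
#'   central rod, with layer indices attached.
#' @export
build_lattice <- function(spec, field, extent) {
  stopifnot(inherits(spec, "lattice_spec"),
            inherits(field, "orientation_field"), extent > 0)
  b <- .lattice_basis(spec)
  l <- spec$l_xy_star
  lz <- spec$l_z_star
  K <- ceiling(extent / lz)
  if (!is.null(spec$n_stack)) K <- min(K, (spec$n_stack - 1L) %/% 2L)
  pos <- vector("list", 2 * K + 1)
  lay <- vector("list", 2 * K + 1)
  row_h <- if (spec$hexagonal) l * sqrt(3) / 2 else l
  for (k in -K:K) {
    z <- k * lz
    rmax2 <- extent^2 - z^2
    if (rmax2 < 0) next
    sh <- b$shifts[[.registry(k, spec$period) + 1]]
    nr <- ceiling(sqrt(rmax2) / row_h) + 2
    ij <- expand.grid(i = -nr:nr, j = -nr:nr)
    x <- ij$i * b$a1[1] + ij$j * b$a2[1] + sh[1]
    y <- ij$i * b$a1[2] + ij$j * b$a2[2] + sh[2]
    keep <- x^2 + y^2 <= rmax2
    if (!any(keep)) next
    pos[[k + K + 1]] <- cbind(x[keep], y[keep], z)
    lay[[k + K + 1]] <- rep.int(k, sum(keep))
  }
  pos <- do.call(rbind, pos)
  lay <- unlist(lay)
  # move the central rod (origin, layer 0) to the front
  ctr <- which(lay == 0L & rowSums(pos^2) < 1e-20)[1]
  if (is.na(ctr)) stop("central rod not found; extent too small?")
  ord <- c(ctr, setdiff(seq_len(nrow(pos)), ctr))
  pos <- pos[ord, , drop = FALSE]
  lay <- lay[ord]
  ori <- layer_orientation(lay, field)
  rod_configuration(pos, ori, box = NULL, periodic = FALSE, layer = lay)
}

# smallest n with n * theta1 = 0 (mod 360), for commensurability checks
.twist_period <- function(theta1, tol = 1e-9) {
  th <- theta1 %% 360
  if (th < tol || 360 - th < tol) return(1L)
  for (n in 1:360) {
    r <- (n * th) %% 360
    if (r < tol || 360 - r < tol) return(as.integer(n))
  }
  NA_integer_
}

#' Build a periodic supercell
#'
#' Tiles the crystal into a cuboid periodic box: the triangular lattice is
#' held in rectangular two-rod cells of size \eqn{\sqrt3\,l_{xy} \times
#' l_{xy}} (or \eqn{l_{xy} \times l_{xy}} one-rod cells for square-based
#' stacks), repeated \code{n_x} by \code{n_y} times in plane and
#' \code{n_z} layers along z. The number density equals
#' \code{spec$rho_star} exactly by construction.
#'
#' \code{n_z} must be a multiple of both the stacking period and the
#' orientation period \eqn{360/\gcd(\Theta_1, 360)} so that registry and
#' twist wrap seamlessly across the z boundary.
#'
#' @param spec a [lattice_spec()].
#' @param field an [orientation_field()].
#' @param n_x,n_y,n_z repetitions of the rectangular cell in x, y and of
#'   the layer in z.
#' @return A periodic [rod_configuration()] with layer indices attached.
#' @export
build_periodic_supercell <- function(spec, field, n_x, n_y, n_z) {
  stopifnot(inherits(spec, "lattice_spec"),
            inherits(field, "orientation_field"),
            n_x >= 1, n_y >= 1, n_z >= 1)
  tp <- .twist_period(field$theta1)
  if (is.na(tp))
    stop("twist angle theta1 is incommensurate with a periodic box")
  if (n_z %% spec$period != 0)
    stop(sprintf("n_z = %d is not a multiple of the %s stacking period %d",
                 n_z, spec$stacking, spec$period))
  if (n_z %% tp != 0)
    stop(sprintf("n_z = %d is not a multiple of the twist period %d", n_z, tp))
  b <- .lattice_basis(spec)
  l <- spec$l_xy_star
  lz <- spec$l_z_star
  if (spec$hexagonal) {
    cell <- c(sqrt(3) * l, l)
    in_cell <- rbind(c(0, 0), c(b$a1[1], b$a1[2]))
  } else {
    cell <- c(l, l)
    in_cell <- rbind(c(0, 0))
  }
  pos <- vector("list", n_z)
  lay <- vector("list", n_z)
  g <- expand.grid(ix = 0:(n_x - 1), iy = 0:(n_y - 1))
  for (k in 0:(n_z - 1)) {
    sh <- b$shifts[[.registry(k, spec$period) + 1]]
    xy <- do.call(rbind, lapply(seq_len(nrow(in_cell)), function(m)
      cbind(g$ix * cell[1] + in_cell[m, 1] + sh[1],
            g$iy * cell[2] + in_cell[m, 2] + sh[2])))
    pos[[k + 1]] <- cbind(xy, k * lz)
    lay[[k + 1]] <- rep.int(k, nrow(xy))
  }
  pos <- do.call(rbind, pos)
  lay <- unlist(lay)
  ori <- layer_orientation(lay, field)
  rod_configuration(pos, ori, box = c(n_x * cell[1], n_y * cell[2], n_z * lz),
                    periodic = TRUE, layer = lay)
}
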