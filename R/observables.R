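#' Nematic order parameters from the orientation tensor
#'
#' Builds the traceless symmetric tensor \eqn{Q = (3\langle \hat v \otimes
#' \hat v\rangle - I)/2} (Maier--Saupe normalisation) and diagonalises it.
#' The uniaxial order parameter \eqn{S} is the largest eigenvalue (1 for
#' perfect alignment, 0 for isotropy, \eqn{-1/2} for planar-isotropic);
#' the biaxial order parameter \eqn{B} is the difference between the two
#' subsequent eigenvalues. Head--tail symmetry of the rods is automatic
#' in this even-order tensor.
#'
#' @param orientations N x 3 matrix of unit vectors (N >= 2), or a
#'   [rod_configuration()].
#' @return An object of class \code{"order_parameters"}: \code{S},
#'   \code{B}, the sorted \code{eigenvalues} (descending, summing to 0)
#'   and the \code{director} (eigenvector of the largest eigenvalue).
#' @examples
#' q_tensor_order(matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE))
#' @export
q_tensor_order <- function(orientations) {
  if (inherits(orientations, "rod_config"))
    orientations <- orientations$orientations
  v <- as.matrix(orientations)
  stopifnot(ncol(v) == 3, nrow(v) >= 2)
  if (any(abs(rowSums(v^2) - 1) > 1e-8))
    stop("orientation vectors must be unit length")
  A <- crossprod(v) / nrow(v)        # <v (x) v>
  Q <- (3 * A - diag(3)) / 2
  ev <- eigen(Q, symmetric = TRUE)
  structure(
    list(S = ev$values[1], B = ev$values[2] - ev$values[3],
         eigenvalues = ev$values, director = ev$vectors[, 1]),
    class = "order_parameters")
}

#' @export
print.order_parameters <- function(x, ...) {
  cat(sprintf("S = %.4f, B = %.4f (eigenvalues %.4f, %.4f, %.4f)\n",
              x$S, x$B, x$eigenvalues[1], x$eigenvalues[2],
              x$eigenvalues[3]))
  invisible(x)
}

#' Radial pair-correlation function of rod centres
#'
#' Standard g(r) over rod centres with minimum-image distances in the
#' periodic box, normalised by the ideal-gas shell counts at the same
#' density.
#'
#' @param config a periodic [rod_configuration()].
#' @param bin_width histogram bin width (reduced length).
#' @param r_max maximum distance; defaults to (and must not exceed) half
#'   the smallest box edge.
#' @return An object of class \code{"pair_correlation"}: data frame with
#'   bin centres \code{r} and \code{g}, plus attributes.
#' @export
pair_correlation <- function(config, bin_width = 0.02, r_max = NULL) {
  stopifnot(inherits(config, "rod_config"), config$periodic)
  L <- config$box
  if (is.null(r_max)) r_max <- min(L) / 2
  if (r_max > min(L) / 2 + 1e-12)
    stop("r_max must not exceed half the smallest box edge")
  p <- config$positions
  n <- nrow(p)
  stopifnot(n >= 2)
  # minimum-image pair distances
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(p[, k], p[, k], "-")
    dk <- dk - L[k] * round(dk / L[k])
    d2 <- d2 + dk^2
  }
  d <- sqrt(d2[upper.tri(d2)])
  d <- d[d < r_max]
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  h <- graphics::hist(d, breaks = edges, plot = FALSE)
  rho <- n / prod(L)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- h$counts / (0.5 * n * rho * shell)
  structure(data.frame(r = h$mids, g = g),
            class = c("pair_correlation", "data.frame"),
            bin_width = bin_width, r_max = r_max, n = n, rho_star = rho)
}

#' @export
plot.pair_correlation <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (reduced)",
                 ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
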