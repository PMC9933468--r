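#' Energy per particle of a crystal + orientation-field candidate
#'
#' Sums the pairwise interactions of one central rod with every rod of the
#' lattice inside the rod cutoff (a spherical cluster built by
#' [build_lattice()]). For the commensurate twist angles used throughout
#' (\eqn{\Theta_1 \in \{0, 60, 120, 180\}} degrees) every layer
#' environment is equivalent, so the central rod of layer 0 represents all
#' rods. No 1/2 double-counting factor is applied: the value is the
#' central rod's total interaction energy, a convention that cancels in
#' all structure comparisons at equal density.
#'
#' @param spec a [lattice_spec()].
#' @param field an [orientation_field()].
#' @param params a [potential_params()].
#' @return An object of class \code{"energy_breakdown"}: reduced energies
#'   per particle \code{u_total} = \code{u_intra} (partners in the central
#'   rod's layer) + \code{u_inter} (all other layers), per-shell
#'   contributions \code{u_shell} (grouped by rounded centre distance) and
#'   the first-shell part \code{u_first}; cluster size as \code{n_rods}.
#' @examples
#' p <- potential_params(kappa_star = 50, M = 7)
#' s <- lattice_spec("ABC", 1 / 3, rho_star = 10)
#' energy_per_particle(s, orientation_field(0), p)
#' @export
energy_per_particle <- function(spec, field, params) {
  stopifnot(inherits(params, "potential_params"))
  rcut <- truncation_radii(params, spec$rho_star)$rod_cutoff
  cfg <- build_lattice(spec, field, rcut)
  e <- .u_scale(params) *
    cpp_central_energies(cfg$positions, cfg$orientations, 0L,
                         params$kappa_star, params$M)
  lay <- cfg$layer
  d <- sqrt(rowSums(cfg$positions^2))
  intra <- lay == 0L
  intra[1] <- FALSE
  shell_id <- round(d / spec$l_xy_star, 3)
  u_shell <- tapply(e[-1], shell_id[-1], sum)
  structure(
    list(u_total = sum(e), u_intra = sum(e[intra]),
         u_inter = sum(e[!intra]) - e[1],
         u_shell = u_shell, u_first = u_shell[[1]],
         n_rods = nrow(cfg$positions), rod_cutoff = rcut,
         spec = spec, field = field),
    class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy per particle (units beta*u*a/(Z^2 lambda)):\n"))
  cat(sprintf("  u_total = %.6g  (intra %.6g + inter %.6g)\n",
              x$u_total, x$u_intra, x$u_inter))
  cat(sprintf("  first-shell part %.3g%%, cluster of %d rods within %.3g\n",
              100 * x$u_first / x$u_total, x$n_rods, x$rod_cutoff))
  invisible(x)
}

# fast path used by the scans: plain numeric u_total
.u_pp <- function(stacking, l_xy, rho_star, field, params) {
  spec <- lattice_spec(stacking, l_xy, rho_star)
  rcut <- truncation_radii(params, rho_star)$rod_cutoff
  cfg <- build_lattice(spec, field, rcut)
  .u_scale(params) *
    sum(cpp_central_energies(cfg$positions, cfg$orientations, 0L,
                             params$kappa_star, params$M))
}

# Interior local minima of a discrete curve.  Two filters guard against
# artifacts: a relative prominence threshold (cutoff-truncation jitter),
# and a value cap relative to the global minimum -- the steep flanks of
# lattice scans carry genuine but irrelevant oscillatory dips (end-to-end
# near-contacts cycling through successive layers) orders of magnitude
# above any competitive structure.
.grid_minima <- function(x, u, min_prominence = 0.005, max_excess = Inf) {
  n <- length(u)
  idx <- which(diff(sign(diff(u))) == 2) + 1
  u_best <- min(u)
  keep <- vapply(idx, function(i) {
    lo <- u[i]
    if (lo > max_excess * u_best) return(FALSE)
    # prominence: smallest barrier separating this minimum from lower ground
    prom_side <- function(side) {
      lower <- which(side < lo)
      if (!length(lower)) return(Inf)
      max(side[seq_len(lower[1])]) - lo
    }
    prom <- min(prom_side(rev(u[seq_len(i - 1)])),
                prom_side(u[seq(i + 1, n)]))
    prom / max(abs(lo), .Machine$double.eps) >= min_prominence
  }, logical(1))
  idx[keep]
}

#' Scan the lattice parameter for energy minima
#'
#' Evaluates the energy per particle on a grid of the in-plane lattice
#' parameter \eqn{l_{xy}^*} at fixed density, tilt and twist (the layer
#' spacing follows from the density constraint), then refines every local
#' minimum by golden-section search. Minima are classified
#' \code{"primary"}/\code{"secondary"} by energy rank, and the barrier
#' between adjacent minima is the maximum of the curve between them minus
#' the shallower minimum.
#'
#' @param stacking lattice stacking (see [lattice_spec()]).
#' @param field an [orientation_field()].
#' @param params a [potential_params()].
#' @param rho_star reduced density.
#' @param l_xy_range bracket for the scan; the default scales with
#'   \eqn{(\rho^*)^{-1/3}} so that both flanks rise.
#' @param n_grid number of coarse grid points (at least 60 by default so
#'   that double-minimum curves are resolved before local refinement).
#' @param refine_tol relative tolerance of the golden-section refinement.
#' @param min_prominence relative prominence below which a grid minimum is
#'   discarded as cutoff-truncation noise.
#' @param max_excess minima whose energy exceeds this multiple of the
#'   global minimum are dropped: the steep flanks carry real but
#'   uncompetitive oscillatory dips (successive layers' end-to-end
#'   near-contacts) far above any candidate ground state.
#' @return An object of class \code{"lxy_scan"}: the grid (\code{l_xy},
#'   \code{u}), a data frame \code{minima} (refined \code{l_xy}, \code{u},
#'   \code{l_z}, classification) and \code{barriers} between adjacent
#'   minima.
#' @export
scan_lxy <- function(stacking, field, params, rho_star,
                     l_xy_range = c(0.55, 3.2) * rho_star^(-1 / 3),
                     n_grid = 60, refine_tol = 1e-4,
                     min_prominence = 0.005, max_excess = 4) {
  stopifnot(length(l_xy_range) == 2, l_xy_range[1] > 0,
            diff(l_xy_range) > 0, n_grid >= 10)
  lx <- seq(l_xy_range[1], l_xy_range[2], length.out = n_grid)
  f <- function(l) .u_pp(stacking, l, rho_star, field, params)
  u <- vapply(lx, f, numeric(1))
  if (which.min(u) %in% c(1L, length(u)))
    warning("no interior minimum in l_xy range; widen the bracket")
  idx <- .grid_minima(lx, u, min_prominence, max_excess)
  minima <- do.call(rbind, lapply(idx, function(i) {
    o <- stats::optimize(f, c(lx[max(1, i - 1)], lx[min(length(lx), i + 1)]),
                         tol = refine_tol * lx[i])
    data.frame(l_xy = o$minimum, u = o$objective)
  }))
  if (is.null(minima)) {
    minima <- data.frame(l_xy = numeric(0), u = numeric(0),
                         l_z = numeric(0), class = character(0))
    barriers <- data.frame(from = numeric(0), to = numeric(0),
                           u_barrier = numeric(0), delta_u = numeric(0))
  } else {
    hex <- stacking %in% c("AAA", "ABA", "ABC")
    minima$l_z <- if (hex) 2 / (sqrt(3) * rho_star * minima$l_xy^2)
                  else 1 / (rho_star * minima$l_xy^2)
    rk <- rank(minima$u, ties.method = "first")
    minima$class <- c("primary", "secondary",
                      paste0("rank", 3:10))[rk]
    m <- minima[order(minima$l_xy), ]
    barriers <- NULL
    if (nrow(m) > 1) {
      barriers <- do.call(rbind, lapply(seq_len(nrow(m) - 1), function(i) {
        span <- lx >= m$l_xy[i] & lx <= m$l_xy[i + 1]
        u_top <- max(u[span])
        data.frame(from = m$l_xy[i], to = m$l_xy[i + 1], u_barrier = u_top,
                   delta_u = u_top - max(m$u[i], m$u[i + 1]))
      }))
    } else {
      barriers <- data.frame(from = numeric(0), to = numeric(0),
                             u_barrier = numeric(0), delta_u = numeric(0))
    }
  }
  structure(
    list(l_xy = lx, u = u, minima = minima, barriers = barriers,
         stacking = stacking, field = field, rho_star = rho_star,
         params = params),
    class = "lxy_scan")
}

#' @export
print.lxy_scan <- function(x, ...) {
  cat(sprintf("l_xy* scan, %s at rho* = %g, phi = %g, Theta1 = %g, kappa* = %g\n",
              x$stacking, x$rho_star, x$field$phi, x$field$theta1,
              x$params$kappa_star))
  if (nrow(x$minima)) {
    print(x$minima, row.names = FALSE, digits = 4)
  } else cat("  no interior local minima found\n")
  invisible(x)
}

#' @export
plot.lxy_scan <- function(x, ..., log = "y") {
  graphics::plot(x$l_xy, x$u, type = "l", log = log,
                 xlab = expression(l["xy"]^"*"),
                 ylab = expression(beta * u[p] * a / (Z^2 * lambda)), ...)
  if (nrow(x$minima))
    graphics::points(x$minima$l_xy, x$minima$u, pch = 19,
                     col = ifelse(x$minima$class == "primary", 2, 4))
  invisible(x)
}

# optimal (l_xy, u) at fixed tilt/twist: coarse grid + refinement of the
# global minimum
.u_opt <- function(stacking, field, params, rho_star,
                   l_xy_range = c(0.55, 3.2) * rho_star^(-1 / 3),
                   n_grid = 48, refine_tol = 1e-4) {
  f <- function(l) .u_pp(stacking, l, rho_star, field, params)
  lx <- seq(l_xy_range[1], l_xy_range[2], length.out = n_grid)
  u <- vapply(lx, f, numeric(1))
  i <- which.min(u)
  o <- stats::optimize(f, c(lx[max(1, i - 1)], lx[min(length(lx), i + 1)]),
                       tol = refine_tol * lx[i])
  c(l_xy = o$minimum, u = o$objective)
}

#' Optimal lattice parameter at fixed tilt and twist
#'
#' Convenience wrapper around the coarse-grid + golden-section search used
#' by the scans: returns the [lattice_spec()] whose \eqn{l_{xy}^*}
#' minimises the energy per particle for the given orientation field.
#'
#' @inheritParams scan_lxy
#' @param n_grid coarse-grid size of the search.
#' @return A list with the optimised \code{spec}, the \code{u} at the
#'   optimum and the \code{field}.
#' @export
optimal_lattice <- function(stacking, field, params, rho_star,
                            l_xy_range = c(0.55, 3.2) * rho_star^(-1 / 3),
                            n_grid = 48) {
  r <- .u_opt(stacking, field, params, rho_star, l_xy_range, n_grid)
  list(spec = lattice_spec(stacking, r[["l_xy"]], rho_star),
       u = r[["u"]], field = field)
}

#' Scan the tilt angle for each candidate structure
#'
#' For every (stacking, \eqn{\Theta_1}) candidate, scans the tilt angle
#' \eqn{\phi} over a grid, re-optimising \eqn{l_{xy}^*} at each tilt via
#' the coarse-grid + golden-section procedure of [scan_lxy()]. Returns the
#' per-structure curves, the lower envelope across structures, interior
#' local minima per structure (refined in \eqn{\phi} with nested
#' \eqn{l_{xy}} optimisation) and barriers between adjacent envelope
#' minima.
#'
#' @param stackings character vector of stackings to scan.
#' @param theta1_set twist angles (degrees) to combine with each stacking.
#' @param params a [potential_params()].
#' @param rho_star reduced density.
#' @param phi_grid tilt grid in degrees (default 0 to 90 by 2.5).
#' @param theta2 start angle (fixed at 0 by default).
#' @param refine logical: refine interior minima in \eqn{\phi}.
#' @param n_grid_lxy grid size of the nested lattice-parameter search.
#' @return An object of class \code{"tilt_scan"} with elements
#'   \code{curves} (long data frame: structure, phi, l_xy, u),
#'   \code{envelope}, \code{minima} and \code{barriers}.
#' @export
scan_tilt <- function(stackings = c("ABC", "ABA"),
                      theta1_set = c(0, 60, 120, 180),
                      params, rho_star,
                      phi_grid = seq(0, 90, by = 2.5), theta2 = 0,
                      refine = TRUE, n_grid_lxy = 48) {
  curves <- list()
  for (st in stackings) for (th1 in theta1_set) {
    key <- sprintf("%s_Th1=%g", st, th1)
    res <- vapply(phi_grid, function(phi)
      .u_opt(st, orientation_field(phi, th1, theta2), params, rho_star,
             n_grid = n_grid_lxy), numeric(2))
    curves[[key]] <- data.frame(structure = key, stacking = st,
                                theta1 = th1, phi = phi_grid,
                                l_xy = res[1, ], u = res[2, ])
  }
  curves <- do.call(rbind, curves)
  rownames(curves) <- NULL
  wide <- do.call(cbind, lapply(split(curves$u, curves$structure), identity))
  # preserve insertion order of structures
  keys <- unique(curves$structure)
  wide <- wide[, keys, drop = FALSE]
  env_u <- apply(wide, 1, min)
  env_str <- keys[apply(wide, 1, which.min)]
  envelope <- data.frame(phi = phi_grid, u = env_u, structure = env_str)

  minima <- NULL
  for (key in keys) {
    cc <- curves[curves$structure == key, ]
    idx <- .grid_minima(cc$phi, cc$u, min_prominence = 0)
    for (i in idx) {
      phi_m <- cc$phi[i]
      u_m <- cc$u[i]
      if (refine) {
        st <- cc$stacking[1]; th1 <- cc$theta1[1]
        fphi <- function(phi)
          .u_opt(st, orientation_field(phi, th1, theta2), params, rho_star,
                 n_grid = n_grid_lxy)["u"]
        o <- stats::optimize(fphi, c(cc$phi[max(1, i - 1)],
                                     cc$phi[min(nrow(cc), i + 1)]),
                             tol = 0.05)
        phi_m <- o$minimum
        u_m <- o$objective
      }
      minima <- rbind(minima, data.frame(structure = key, phi = phi_m,
                                         u = u_m))
    }
  }
  if (is.null(minima))
    minima <- data.frame(structure = character(0), phi = numeric(0),
                         u = numeric(0))
  # barriers along the envelope between its adjacent local minima
  eidx <- sort(unique(c(.grid_minima(envelope$phi, envelope$u, 0),
                        if (envelope$u[1] < envelope$u[2]) 1L,
                        if (envelope$u[length(env_u)] <
                            envelope$u[length(env_u) - 1]) length(env_u))))
  barriers <- NULL
  if (length(eidx) > 1) {
    barriers <- do.call(rbind, lapply(seq_len(length(eidx) - 1), function(i) {
      span <- seq(eidx[i], eidx[i + 1])
      u_top <- max(env_u[span])
      data.frame(phi_from = phi_grid[eidx[i]], phi_to = phi_grid[eidx[i + 1]],
                 u_barrier = u_top,
                 delta_u = u_top - max(env_u[eidx[i]], env_u[eidx[i + 1]]))
    }))
  } else {
    barriers <- data.frame(phi_from = numeric(0), phi_to = numeric(0),
                           u_barrier = numeric(0), delta_u = numeric(0))
  }
  structure(list(curves = curves, envelope = envelope, minima = minima,
                 barriers = barriers, rho_star = rho_star, params = params),
            class = "tilt_scan")
}

#' @export
print.tilt_scan <- function(x, ...) {
  cat(sprintf("tilt scan at rho* = %g, kappa* = %g\n",
              x$rho_star, x$params$kappa_star))
  u0 <- min(x$envelope$u)
  cat(sprintf("  envelope minimum u = %.6g at phi = %g (%s)\n", u0,
              x$envelope$phi[which.min(x$envelope$u)],
              x$envelope$structure[which.min(x$envelope$u)]))
  if (nrow(x$minima)) {
    m <- x$minima
    m$excess_pct <- 100 * (m$u - u0) / u0
    cat("  interior local minima:\n")
    print(m, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
plot.tilt_scan <- function(x, relative = TRUE, ...) {
  u0 <- min(x$envelope$u)
  sp <- split(x$curves, x$curves$structure)
  ylim <- range(vapply(sp, function(d) range(d$u / if (relative) u0 else 1),
                       numeric(2)))
  graphics::plot(NA, xlim = range(x$envelope$phi), ylim = ylim,
                 xlab = expression(phi ~ "(deg)"),
                 ylab = if (relative) expression(u / u[0]) else "u", ...)
  for (i in seq_along(sp))
    graphics::lines(sp[[i]]$phi, sp[[i]]$u / if (relative) u0 else 1,
                    col = i, lty = 2)
  graphics::lines(x$envelope$phi, x$envelope$u / if (relative) u0 else 1,
                  lwd = 2)
  graphics::legend("topleft", legend = names(sp), col = seq_along(sp),
                   lty = 2, cex = 0.7, bty = "n")
  invisible(x)
}

#' Locate the ground state over a candidate set
#'
#' Minimises the energy per particle over stackings, twist angles and a
#' tilt grid, with the lattice parameter re-optimised for every candidate.
#' Candidates within \code{tol_rel} of the minimum are reported as ties
#' (ABA and ABC are frequently degenerate at \eqn{\phi = 0}).
#'
#' @param rho_star,params state point and interaction parameters.
#' @param stackings,theta1_set,phi_grid the candidate set.
#' @param n_grid_lxy nested lattice-parameter grid size.
#' @param tol_rel relative energy window for reporting ties.
#' @return A list of class \code{"ground_state"}: \code{best} (one-row
#'   data frame), \code{ties}, and the full candidate \code{table}.
#' @export
find_ground_state <- function(rho_star, params,
                              stackings = c("AAA", "ABA", "ABC"),
                              theta1_set = c(0, 60, 120, 180),
                              phi_grid = seq(0, 90, by = 5),
                              n_grid_lxy = 48, tol_rel = 1e-3) {
  rows <- list()
  for (st in stackings) {
    for (phi in phi_grid) {
      th_set <- if (phi == 0) 0 else theta1_set  # twist is moot at phi = 0
      for (th1 in th_set) {
        r <- .u_opt(st, orientation_field(phi, th1), params, rho_star,
                    n_grid = n_grid_lxy)
        rows[[length(rows) + 1]] <-
          data.frame(stacking = st, theta1 = th1, phi = phi,
                     l_xy = r[["l_xy"]], u = r[["u"]])
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$u), ]
  rownames(tab) <- NULL
  best <- tab[1, ]
  ties <- tab[tab$u <= best$u * (1 + tol_rel), ]
  structure(list(best = best, ties = ties, table = tab,
                 rho_star = rho_star, params = params),
            class = "ground_state")
}

#' @export
print.ground_state <- function(x, ...) {
  cat(sprintf("ground state at rho* = %g, kappa* = %g:\n",
              x$rho_star, x$params$kappa_star))
  print(x$best, row.names = FALSE, digits = 5)
  if (nrow(x$ties) > 1) {
    cat("  degenerate within tolerance:\n")
    print(x$ties, row.names = FALSE, digits = 5)
  }
  invisible(x)
}

#' Closest end-segment separation in the piercing geometry
#'
#' When end segments of rods from a neighbouring layer pierce the hexagonal
#' layer below, the closest segment-to-segment distance is bounded below by
#' \eqn{l_{xy}^* \sqrt3 / 4}.
#'
#' @param l_xy_star in-plane lattice parameter (reduced).
#' @return The reduced distance \eqn{l_{xy}^* \sqrt3/4}.
#' @export
closest_end_separation <- function(l_xy_star) {
  stopifnot(l_xy_star >= 0)
  l_xy_star * sqrt(3) / 4
}
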