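#' Monte Carlo run configuration
#'
#' Settings for NVT Metropolis Monte Carlo. At \code{temperature = 0} the
#' runs are greedy stochastic minimisation: only moves that lower the
#' energy are accepted. One MC step is either \code{N} single-rod trial
#' moves (displacement, rotation or combined displacement-rotation, chosen
#' uniformly among the enabled kinds) or, every \code{box_every}-th step
#' when enabled, 9 isochoric box-dimension trials: one box length is
#' scaled by a random factor within \eqn{\pm 0.5\%}, a second (random)
#' length is rescaled to conserve the volume and the third is untouched,
#' with all rod centres rescaled affinely.
#'
#' Step sizes adapt multiplicatively toward the target acceptance window
#' during the first \code{tune_steps} steps of every block of
#' \code{block_steps} steps (adjustment every \code{tune_every}-th step)
#' and stay frozen for the rest of the block; blocks repeat for the whole
#' run, so acceptance stays in the window as the system orders.
#'
#' @param temperature reduced temperature (\eqn{k_B T} in units of the
#'   interaction scale \eqn{Z^2\lambda/a}); 0 allowed (greedy descent).
#' @param n_steps number of MC steps.
#' @param move_kinds subset of \code{c("translate", "rotate", "combined")}.
#' @param box_moves enable isochoric box-dimension moves.
#' @param box_every a box-move step every this many steps.
#' @param delta_translate,delta_rotate initial maximum displacement
#'   (reduced length) and rotation angle (radians).
#' @param target_acceptance acceptance window, default 20--50\%.
#' @param tune_steps,tune_every,block_steps the adaptive schedule.
#' @param sample_every record the trace every this many steps.
#' @param snapshot_every store full configurations at this cadence (0 =
#'   only the final one).
#' @param recompute_every refresh the running total energy from scratch at
#'   this cadence (guards accumulation drift).
#' @param debug_check cross-check every accepted local update against a
#'   full energy recompute (slow; for testing).
#' @return An object of class \code{"mc_config"}.
#' @export
mc_config <- function(temperature = 0, n_steps = 1000,
                      move_kinds = c("translate", "rotate", "combined"),
                      box_moves = TRUE, box_every = 10,
                      delta_translate = 0.02, delta_rotate = 0.1,
                      target_acceptance = c(0.2, 0.5),
                      tune_steps = 300, tune_every = 10,
                      block_steps = 1000, sample_every = 10,
                      snapshot_every = 0, recompute_every = 200,
                      debug_check = FALSE) {
  stopifnot(temperature >= 0, n_steps >= 1,
            all(move_kinds %in% c("translate", "rotate", "combined")),
            length(move_kinds) >= 1,
            delta_translate > 0, delta_rotate > 0,
            length(target_acceptance) == 2,
            target_acceptance[1] < target_acceptance[2])
  structure(list(
    temperature = temperature, n_steps = as.integer(n_steps),
    move_kinds = move_kinds, box_moves = isTRUE(box_moves),
    box_every = as.integer(box_every),
    delta_translate = delta_translate, delta_rotate = delta_rotate,
    target_acceptance = target_acceptance,
    tune_steps = as.integer(tune_steps),
    tune_every = as.integer(tune_every),
    block_steps = as.integer(block_steps),
    sample_every = as.integer(sample_every),
    snapshot_every = as.integer(snapshot_every),
    recompute_every = as.integer(recompute_every),
    debug_check = isTRUE(debug_check)), class = "mc_config")
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf("MC config: T* = %g, %d steps, moves {%s}%s\n",
              x$temperature, x$n_steps, paste(x$move_kinds, collapse = ", "),
              if (x$box_moves)
                sprintf(", box moves every %d steps", x$box_every) else ""))
  invisible(x)
}

#' Metropolis acceptance rule
#'
#' At zero temperature only strictly downhill moves are accepted; at
#' finite temperature a move is accepted with probability
#' \eqn{\min(1, e^{-\Delta u / T})} (detailed balance with symmetric
#' proposals).
#'
#' @param delta_u energy change of the trial move (reduced units).
#' @param temperature reduced temperature, >= 0.
#' @return Logical: accept the move. Uses R's RNG stream at finite
#'   temperature.
#' @export
metropolis_accept <- function(delta_u, temperature) {
  stopifnot(length(delta_u) == 1, is.finite(delta_u))
  if (temperature < 0) stop("temperature must be non-negative")
  if (temperature == 0) return(delta_u < 0)
  if (delta_u <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_u / temperature)
}

#' Step-size adjustment rule
#'
#' The multiplicative up/down rule used inside the tuning stage: step
#' sizes grow by 25\% when the windowed acceptance exceeds the target
#' band, shrink by 20\% below it, and are clamped to \code{(0, max)}.
#'
#' @param delta current step size.
#' @param acceptance acceptance rate over the last window.
#' @param target acceptance window (default 20--50\%).
#' @param max_delta upper clamp (e.g. half the smallest box edge).
#' @return The adjusted step size.
#' @export
tune_step_sizes <- function(delta, acceptance, target = c(0.2, 0.5),
                            max_delta = Inf) {
  stopifnot(delta > 0, acceptance >= 0, acceptance <= 1)
  f <- if (acceptance > target[2]) 1.25 else if (acceptance < target[1]) 0.8 else 1
  min(max(delta * f, 1e-7), max_delta)
}

# interaction energy of rod i (1-based) in a periodic configuration,
# including interactions with its own periodic images
.rod_energy <- function(config, i, params) {
  rho <- nrow(config$positions) / prod(config$box)
  rcut <- truncation_radii(params, rho)$rod_cutoff
  .u_scale(params) *
    cpp_rod_energy_pbc(config$positions, config$orientations, config$box,
                       i - 1L, params$kappa_star, params$M, rcut)
}

#' Total energy of a periodic configuration
#'
#' Sum over all rod pairs and periodic images within the rod cutoff
#' (including rods with their own images when the box is smaller than
#' twice the cutoff).
#'
#' @param config a periodic [rod_configuration()].
#' @param params a [potential_params()].
#' @return Total reduced energy (not per particle).
#' @export
total_energy <- function(config, params) {
  stopifnot(inherits(config, "rod_config"), config$periodic)
  rho <- nrow(config$positions) / prod(config$box)
  rcut <- truncation_radii(params, rho)$rod_cutoff
  .u_scale(params) *
    cpp_total_energy_pbc(config$positions, config$orientations, config$box,
                         params$kappa_star, params$M, rcut)
}

#' Propose a single-rod trial move
#'
#' Displaces and/or rotates one rod and returns the proposed configuration
#' together with the local energy change (computed from the moved rod's
#' interactions only, which equals the full energy difference because all
#' other pair energies are untouched). Proposals are symmetric:
#' displacement uniform in a cube of half-width \code{delta_translate},
#' rotation about a uniform random axis by an angle uniform in
#' \code{(0, delta_rotate]}.
#'
#' @param config a periodic [rod_configuration()].
#' @param i rod index (1-based).
#' @param kind \code{"translate"}, \code{"rotate"} or \code{"combined"}.
#' @param params a [potential_params()].
#' @param delta_translate,delta_rotate maximum displacement / rotation.
#' @return A list with the proposed \code{config} and \code{delta_u}.
#' @export
single_rod_move <- function(config, i, kind = c("translate", "rotate",
                                                "combined"),
                            params, delta_translate = 0.02,
                            delta_rotate = 0.1) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "rod_config"), config$periodic,
            i >= 1, i <= nrow(config$positions))
  e_old <- .rod_energy(config, i, params)
  new <- config
  if (kind %in% c("translate", "combined")) {
    dx <- stats::runif(3, -delta_translate, delta_translate)
    p <- new$positions[i, ] + dx
    new$positions[i, ] <- p - new$box * floor(p / new$box)
  }
  if (kind %in% c("rotate", "combined")) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, 0, delta_rotate)
    v <- new$orientations[i, ]
    ct <- cos(th); st <- sin(th)
    v_new <- v * ct + c(ax[2] * v[3] - ax[3] * v[2],
                        ax[3] * v[1] - ax[1] * v[3],
                        ax[1] * v[2] - ax[2] * v[1]) * st +
      ax * sum(ax * v) * (1 - ct)
    new$orientations[i, ] <- v_new / sqrt(sum(v_new^2))
  }
  list(config = new, delta_u = .rod_energy(new, i, params) - e_old)
}

#' Propose an isochoric box-dimension move
#'
#' Scales one randomly chosen box length by a factor uniform within
#' \eqn{\pm 0.5\%}, rescales a second (randomly chosen among the two
#' remaining) to conserve the volume exactly, leaves the third unchanged,
#' and maps all rod centres affinely.
#'
#' @param config a periodic [rod_configuration()].
#' @param params a [potential_params()].
#' @param max_frac maximum relative length change (default 0.005).
#' @return A list with the proposed \code{config} and \code{delta_u}
#'   (from a full energy recompute).
#' @export
box_move <- function(config, params, max_frac = 0.005) {
  stopifnot(inherits(config, "rod_config"), config$periodic)
  d1 <- sample.int(3, 1)
  d2 <- setdiff(1:3, d1)[sample.int(2, 1)]
  f <- 1 + stats::runif(1, -max_frac, max_frac)
  new <- config
  new$box[d1] <- new$box[d1] * f
  new$box[d2] <- new$box[d2] / f
  new$positions[, d1] <- new$positions[, d1] * f
  new$positions[, d2] <- new$positions[, d2] / f
  list(config = new, delta_u = total_energy(new, params) -
         total_energy(config, params))
}

#' Randomly perturb a configuration
#'
#' Adds small uniform position jitter and random orientation kicks. An
#' ideal lattice is a stationary point of the energy by symmetry, so
#' stability tests seed instabilities with a small perturbation; a
#' (meta)stable structure relaxes back, an unstable one escapes.
#'
#' @param config a [rod_configuration()].
#' @param pos_amp maximum displacement per coordinate (reduced length).
#' @param angle_amp_deg maximum rotation angle (degrees).
#' @return The perturbed [rod_configuration()]. Uses R's RNG stream.
#' @export
perturb_configuration <- function(config, pos_amp = 0.01,
                                  angle_amp_deg = 2) {
  stopifnot(inherits(config, "rod_config"))
  n <- nrow(config$positions)
  p <- config$positions +
    matrix(stats::runif(3 * n, -pos_amp, pos_amp), n, 3)
  v <- config$orientations
  ax <- matrix(stats::rnorm(3 * n), n, 3)
  ax <- ax / sqrt(rowSums(ax^2))
  th <- stats::runif(n, 0, angle_amp_deg * pi / 180)
  ct <- cos(th); st <- sin(th)
  dot <- rowSums(ax * v)
  cr <- cbind(ax[, 2] * v[, 3] - ax[, 3] * v[, 2],
              ax[, 3] * v[, 1] - ax[, 1] * v[, 3],
              ax[, 1] * v[, 2] - ax[, 2] * v[, 1])
  v <- v * ct + cr * st + ax * (dot * (1 - ct))
  v <- v / sqrt(rowSums(v^2))
  rod_configuration(p, v, config$box, periodic = config$periodic,
                    layer = config$layer)
}

#' Run NVT Monte Carlo
#'
#' Runs the compiled Metropolis engine on a periodic rod configuration.
#' Uses R's RNG stream: set \code{set.seed()} beforehand for reproducible
#' traces.
#'
#' @param config a periodic [rod_configuration()] (the start state).
#' @param params a [potential_params()]; the interaction cutoff follows
#'   from [truncation_radii()] at the configuration's density.
#' @param mc an [mc_config()].
#' @return An object of class \code{"mc_trace"}: data frame \code{trace}
#'   (step, energy per rod, box lengths, acceptance rates, order
#'   parameters S and B), the \code{final} configuration,
#'   \code{snapshots}, and bookkeeping fields.
#' @export
run_mc <- function(config, params, mc = mc_config()) {
  stopifnot(inherits(config, "rod_config"), config$periodic,
            inherits(params, "potential_params"),
            inherits(mc, "mc_config"))
  n <- nrow(config$positions)
  rho <- n / prod(config$box)
  rcut <- truncation_radii(params, rho)$rod_cutoff
  kinds <- c("translate", "rotate", "combined") %in% mc$move_kinds
  res <- cpp_run_mc(config$positions, config$orientations, config$box,
                    params$kappa_star, params$M, rcut, mc$temperature,
                    mc$n_steps, kinds, mc$box_moves, mc$box_every,
                    mc$delta_translate, mc$delta_rotate,
                    mc$tune_steps, mc$tune_every, mc$block_steps,
                    mc$target_acceptance[1], mc$target_acceptance[2],
                    mc$sample_every, mc$snapshot_every,
                    mc$recompute_every, mc$debug_check)
  scale <- .u_scale(params)
  # order parameters from the sampled second-moment tensors
  SB <- t(apply(res$Qmom, 1, function(q) {
    A <- matrix(c(q[1], q[4], q[5], q[4], q[2], q[6], q[5], q[6], q[3]), 3)
    ev <- sort(eigen((3 * A - diag(3)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    c(S = ev[1], B = ev[2] - ev[3])
  }))
  trace <- data.frame(step = res$step, u = scale * res$u,
                      S = SB[, 1], B = SB[, 2],
                      Lx = res$Lx, Ly = res$Ly, Lz = res$Lz,
                      acc_translate = res$acc_translate,
                      acc_rotate = res$acc_rotate,
                      acc_combined = res$acc_combined,
                      acc_box = res$acc_box)
  final <- rod_configuration(res$positions, res$orientations, res$box,
                             periodic = TRUE, layer = config$layer)
  structure(list(trace = trace, final = final, snapshots = res$snapshots,
                 u_final = scale * res$u_final,
                 delta_final = res$delta_final,
                 mc = mc, params = params, rcut = rcut),
            class = "mc_trace")
}

#' @export
print.mc_trace <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("MC trace: %d sampled steps, T* = %g\n", nrow(tr),
              x$mc$temperature))
  cat(sprintf("  u/rod: %.6g -> %.6g; S: %.3f -> %.3f; B: %.3f -> %.3f\n",
              tr$u[1], tr$u[nrow(tr)], tr$S[1], tr$S[nrow(tr)],
              tr$B[1], tr$B[nrow(tr)]))
  cat(sprintf("  final box %.4g x %.4g x %.4g\n",
              tr$Lx[nrow(tr)], tr$Ly[nrow(tr)], tr$Lz[nrow(tr)]))
  invisible(x)
}

#' @export
plot.mc_trace <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$step, tr$u, type = "l", xlab = "MC step",
                 ylab = "u per rod", ...)
  graphics::matplot(tr$step, cbind(tr$S, tr$B), type = "l", lty = 1,
                    col = c(1, 2), xlab = "MC step", ylab = "S, B")
  graphics::legend("topright", c("S", "B"), col = c(1, 2), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Mean tilt angle of a configuration
#'
#' Average polar angle of the rod axes relative to z, folding head--tail
#' equivalent orientations together (\eqn{\phi} and \eqn{180 - \phi} are
#' the same physical tilt).
#'
#' @param config a [rod_configuration()] (or an N x 3 orientation matrix).
#' @return Mean tilt in degrees, in \[0, 90\].
#' @export
mean_tilt_angle <- function(config) {
  v <- if (inherits(config, "rod_config")) config$orientations else config
  mean(acos(pmin(1, abs(v[, 3])))) * 180 / pi
}

#' Simple (meta)stability verdict for an MC trace
#'
#' A configuration is regarded as (meta-)stable when the uniaxial order
#' parameter at the end of the run remains within a tolerance of its
#' starting value (thermal broadening only); a collapse or drift of S
#' flags instability.
#'
#' @param x an [run_mc()] trace.
#' @param tol_S tolerance on the change in S.
#' @return Logical verdict with attribute \code{dS}.
#' @export
mc_stable <- function(x, tol_S = 0.05) {
  stopifnot(inherits(x, "mc_trace"))
  tr <- x$trace
  dS <- abs(tr$S[nrow(tr)] - tr$S[1])
  structure(dS <= tol_S, dS = dS)
}
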