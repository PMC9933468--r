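# a small periodic crystal used across the MC tests
mc_fixture <- function(l = 0.55, rho = 10, phi = 0, th1 = 0,
                       nx = 2, ny = 2, nz = 4) {
  s <- lattice_spec("AAA", l, rho)
  build_periodic_supercell(s, orientation_field(phi, th1), nx, ny, nz)
}
p_mc <- potential_params(kappa_star = 20, M = 3, n_trunc = 3)

test_that("metropolis rule: strict descent at T = 0, Boltzmann at T > 0", {
  expect_true(metropolis_accept(-1, 0))
  expect_true(metropolis_accept(-1, 5))
  expect_false(metropolis_accept(1e-12, 0))
  expect_false(metropolis_accept(0, 0))
  expect_error(metropolis_accept(1, -1), "non-negative")
  # du = T log(2): long-run acceptance 1/2
  set.seed(2)
  acc <- mean(replicate(4000, metropolis_accept(0.693147 * 2, 2)))
  expect_equal(acc, 0.5, tolerance = 0.05)
})

test_that("step-size tuning moves toward the target window", {
  expect_gt(tune_step_sizes(0.1, 0.8), 0.1)
  expect_equal(tune_step_sizes(0.1, 0.35), 0.1)
  expect_lt(tune_step_sizes(0.1, 0.05), 0.1)
  expect_lte(tune_step_sizes(1, 0.9, max_delta = 1.1), 1.1)
})

test_that("local move energy difference equals a full recompute", {
  cfg <- mc_fixture()
  set.seed(4)
  cfg <- perturb_configuration(cfg, 0.02, 5)
  u0 <- total_energy(cfg, p_mc)
  for (kind in c("translate", "rotate", "combined")) {
    mv <- single_rod_move(cfg, 3, kind, p_mc,
                          delta_translate = 0.05, delta_rotate = 0.3)
    expect_equal(mv$delta_u, total_energy(mv$config, p_mc) - u0,
                 tolerance = 1e-9 * abs(u0))
    # rotations preserve unit orientations
    expect_equal(rowSums(mv$config$orientations^2),
                 rep(1, nrow(cfg$positions)), tolerance = 1e-12)
  }
})

test_that("the compiled image-summed energy matches a naive R image loop", {
  cfg <- mc_fixture(nx = 2, ny = 2, nz = 3)
  set.seed(8)
  cfg <- perturb_configuration(cfg, 0.03, 10)
  expect_equal(total_energy(cfg, p_mc), naive_total_energy_pbc(cfg, p_mc),
               tolerance = 1e-10)
})

test_that("box moves conserve the volume and scale affinely", {
  cfg <- mc_fixture()
  set.seed(6)
  for (i in 1:5) {
    mv <- box_move(cfg, p_mc)
    expect_equal(prod(mv$config$box), prod(cfg$box), tolerance = 1e-12)
    # one dimension untouched
    expect_equal(sum(abs(mv$config$box - cfg$box) < 1e-15), 1)
    # fractional coordinates unchanged
    expect_equal(mv$config$positions / matrix(mv$config$box,
                                              nrow(cfg$positions), 3,
                                              byrow = TRUE),
                 cfg$positions / matrix(cfg$box, nrow(cfg$positions), 3,
                                        byrow = TRUE), tolerance = 1e-12)
  }
})

test_that("T = 0 runs strictly descend and stay put at a relaxed state", {
  cfg <- mc_fixture()
  set.seed(10)
  cfg <- perturb_configuration(cfg, 0.01, 2)
  res <- run_mc(cfg, p_mc, mc_config(temperature = 0, n_steps = 300,
                                     sample_every = 5, box_every = 20,
                                     debug_check = TRUE,
                                     recompute_every = 0))
  u <- res$trace$u
  expect_true(all(diff(u) <= 1e-12 * abs(u[1])))   # monotone descent
  drop1 <- u[1] - res$u_final
  expect_gt(drop1, 0)
  # a second leg from the relaxed state recovers far less energy
  res2 <- run_mc(res$final, p_mc, mc_config(temperature = 0, n_steps = 150,
                                            sample_every = 10))
  expect_lt(res2$trace$u[1] - res2$u_final, 0.1 * drop1)
})

test_that("identical seed and config reproduce the trace exactly", {
  cfg <- mc_fixture()
  run1 <- {
    set.seed(33)
    run_mc(perturb_configuration(cfg, 0.02, 5), p_mc,
           mc_config(temperature = 0.001, n_steps = 40, sample_every = 5))
  }
  run2 <- {
    set.seed(33)
    run_mc(perturb_configuration(cfg, 0.02, 5), p_mc,
           mc_config(temperature = 0.001, n_steps = 40, sample_every = 5))
  }
  expect_identical(run1$trace, run2$trace)
  expect_identical(run1$final$positions, run2$final$positions)
})

test_that("finite-T sampling matches direct Boltzmann quadrature (2 rods)", {
  # two parallel rods, one mobile: the sampled mean energy must match the
  # Boltzmann average over the mobile rod's position computed on a grid
  L <- c(1.2, 1.2, 1.2)
  p2 <- potential_params(kappa_star = 8, M = 1, n_trunc = 2)
  pos <- rbind(c(0, 0, 0), c(0.6, 0.6, 0.6))
  ori <- rbind(c(0, 0, 1), c(0, 0, 1))
  cfg <- rod_configuration(pos, ori, box = L)
  Tred <- 0.6
  # exhaustive grid integration of <u> over the relative position
  ng <- 24
  xs <- (seq_len(ng) - 0.5) / ng * L[1]
  u_of <- function(x, y, z) {
    c2 <- cfg; c2$positions[2, ] <- c(x, y, z)
    total_energy(c2, p2)
  }
  us <- numeric(0)
  for (x in xs) for (y in xs) for (z in xs) us <- c(us, u_of(x, y, z))
  w <- exp(-us / Tred)
  u_exact <- sum(us * w) / sum(w)
  set.seed(77)
  res <- run_mc(cfg, p2, mc_config(temperature = Tred, n_steps = 8000,
                                   move_kinds = "translate",
                                   box_moves = FALSE, sample_every = 2,
                                   recompute_every = 100))
  u_mc <- mean(res$trace$u[res$trace$step > 1000] * 2)  # per rod -> total
  expect_equal(u_mc, u_exact, tolerance = 0.05)
})

test_that("box moves allow anisotropic in-plane distortion of tilted AAA", {
  # tilted unidirectional AAA (rods along x): the x box length decouples
  # from y under isochoric moves at T = 0
  p <- potential_params(kappa_star = 20, M = 3, n_trunc = 3)
  opt <- optimal_lattice("AAA", orientation_field(60, 0), p, 10)
  cfg <- build_periodic_supercell(opt$spec, opt$field, 2, 3, 6)
  set.seed(21)
  cfg <- perturb_configuration(cfg, 0.01, 2)
  asp0 <- cfg$box[1] / cfg$box[2] / (cfg$box[1] / cfg$box[2])
  res <- run_mc(cfg, p, mc_config(temperature = 0, n_steps = 400,
                                  box_every = 2, sample_every = 20))
  tr <- res$trace
  rel_change <- abs((tr$Lx[nrow(tr)] / tr$Ly[nrow(tr)]) /
                      (tr$Lx[1] / tr$Ly[1]) - 1)
  expect_gt(rel_change, 0.005)   # the x/y aspect drifted
  expect_lt(res$u_final, tr$u[1])
})
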