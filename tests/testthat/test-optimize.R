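# cheap settings: high kappa* (small clusters) and few segments
p_fast <- potential_params(kappa_star = 50, M = 5, n_trunc = 6)

test_that("energy per particle equals the naive all-pairs cluster sum", {
  for (case in list(list("ABC", 0.35, orientation_field(0)),
                    list("AAA", 0.65, orientation_field(80, 120)))) {
    s <- lattice_spec(case[[1]], case[[2]], rho_star = 10)
    eb <- energy_per_particle(s, case[[3]], p_fast)
    cl <- build_lattice(s, case[[3]],
                        truncation_radii(p_fast, 10)$rod_cutoff)
    expect_lt(nrow(cl$positions), 500)
    expect_equal(eb$u_total, naive_central_energy(cl, p_fast),
                 tolerance = 1e-12)
    # decomposition invariants
    expect_equal(eb$u_total, eb$u_intra + eb$u_inter, tolerance = 1e-12)
    expect_equal(eb$u_total, sum(eb$u_shell), tolerance = 1e-12)
    expect_lte(eb$u_first, eb$u_total)
    expect_gte(eb$u_intra, 0)
    expect_gte(eb$u_inter, 0)
  }
})

test_that("truncated energies grow monotonically with n_trunc", {
  s <- lattice_spec("ABC", 0.35, 10)
  f <- orientation_field(0)
  us <- sapply(c(2, 4, 6, 8), function(nt)
    energy_per_particle(s, f, potential_params(20, M = 3,
                                               n_trunc = nt))$u_total)
  expect_true(all(diff(us) > 0))   # only positive terms are added
  # and the increments shrink (convergence from below)
  expect_true(all(diff(diff(us)) < 0))
})

test_that("energy is periodic in Theta2 with period 60 degrees", {
  s <- lattice_spec("AAA", 0.6, 10)
  p <- potential_params(30, M = 3, n_trunc = 4)
  u <- sapply(c(0, 17, 60, 77), function(t2)
    energy_per_particle(s, orientation_field(75, 120, t2), p)$u_total)
  expect_equal(u[1], u[3], tolerance = 1e-10)
  expect_equal(u[2], u[4], tolerance = 1e-10)
  expect_gt(abs(u[1] - u[2]) / u[1], 1e-6)  # but not constant in Theta2
})

test_that("lattice-parameter scan finds and classifies the known minima", {
  p <- potential_params(kappa_star = 50, M = 7, n_trunc = 10)
  sc_abc <- scan_lxy("ABC", orientation_field(0), p, rho_star = 10)
  expect_equal(nrow(sc_abc$minima), 2)
  expect_equal(sc_abc$minima$class[order(sc_abc$minima$u)],
               c("primary", "secondary"))
  prim <- sc_abc$minima[sc_abc$minima$class == "primary", ]
  sec <- sc_abc$minima[sc_abc$minima$class == "secondary", ]
  expect_lt(abs(prim$l_xy - 1 / 3), 0.05)
  expect_lt(abs(sec$l_xy - 1 / 2), 0.05)
  # density invariant on the reported minima
  expect_equal(prim$l_z, 2 / (sqrt(3) * 10 * prim$l_xy^2))
  # a barrier separates them
  expect_gt(sc_abc$barriers$delta_u[1], 0)
  sc_aaa <- scan_lxy("AAA", orientation_field(80, 120), p, rho_star = 10)
  expect_equal(nrow(sc_aaa$minima), 1)
  expect_lt(abs(sc_aaa$minima$l_xy - 2 / 3), 0.05)
})

test_that("log-energy flanks of the scan are close to linear", {
  p <- potential_params(kappa_star = 50, M = 5, n_trunc = 8)
  sc <- scan_lxy("ABC", orientation_field(0), p, 10,
                 l_xy_range = c(0.2, 0.45), n_grid = 30)
  lu <- log(sc$u)
  i_min <- which.min(sc$u)
  left <- 2:(i_min - 1)
  curv <- abs(diff(diff(lu[left])))
  slope <- abs(mean(diff(lu[left])))
  expect_lt(stats::median(curv) / slope, 0.2)
})

test_that("closest end separation follows the piercing-geometry bound", {
  expect_equal(closest_end_separation(0.34), 0.34 * sqrt(3) / 4)
  expect_equal(closest_end_separation(0.34), 0.147, tolerance = 1e-2)
  expect_equal(closest_end_separation(0), 0)
  expect_equal(closest_end_separation(4 / sqrt(3)), 1)
})

test_that("relative minima ordering is stable under M refinement", {
  # secondary vs primary vs heliconical-AAA ranking persists for M = 3..7
  rank_u <- sapply(c(3, 5, 7), function(M) {
    p <- potential_params(50, M = M, n_trunc = 6)
    c(.u <- NA,
      abc1 = energy_per_particle(lattice_spec("ABC", 0.316, 10),
                                 orientation_field(0), p)$u_total,
      abc2 = energy_per_particle(lattice_spec("ABC", 0.534, 10),
                                 orientation_field(0), p)$u_total,
      aaa = energy_per_particle(lattice_spec("AAA", 0.631, 10),
                                orientation_field(80, 120), p)$u_total)[-1]
  })
  for (j in 1:3) expect_true(all(order(rank_u[, j]) == 1:3))
})

test_that("square-based lattices are beaten by their hexagonal versions", {
  p <- potential_params(kappa_star = 20, M = 5, n_trunc = 6)
  f <- orientation_field(0)
  u_hex <- optimal_lattice("ABC", f, p, 10)$u
  u_cub <- optimal_lattice("cubicABA", f, p, 10)$u
  u_hex_aaa <- optimal_lattice("AAA", f, p, 10)$u
  u_cub_aaa <- optimal_lattice("cubicAAA", f, p, 10)$u
  expect_lt(u_hex, u_cub)
  expect_lt(u_hex_aaa, u_cub_aaa)
})
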