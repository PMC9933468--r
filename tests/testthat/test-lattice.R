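test_that("layer orientation follows the spherical parametrisation", {
  # pole degeneracy: phi = 0 gives +z for every layer
  f0 <- orientation_field(0, theta1 = 77, theta2 = 13)
  for (k in 0:4)
    expect_equal(drop(layer_orientation(k, f0)), c(0, 0, 1))
  # direct evaluation
  f <- orientation_field(90, theta1 = 60, theta2 = 0)
  expect_equal(drop(layer_orientation(1, f)),
               c(cos(pi / 3), sin(pi / 3), 0), tolerance = 1e-12)
  # twist period: Theta1 = 120 repeats after 3 layers
  f3 <- orientation_field(40, theta1 = 120)
  expect_equal(layer_orientation(0:2, f3), layer_orientation(3:5, f3))
})

test_that("density constraint fixes the layer spacing", {
  s <- lattice_spec("ABC", l_xy_star = 0.5, rho_star = 10)
  expect_equal(s$l_z_star, 2 / (sqrt(3) * 10 * 0.25))
  expect_equal(s$l_z_star, 0.4619, tolerance = 1e-4)
  sq <- lattice_spec("cubicAAA", l_xy_star = 0.5, rho_star = 10)
  expect_equal(sq$l_z_star, 1 / (10 * 0.25))
  expect_error(lattice_spec("ABC", -1, 10))
})

test_that("cluster geometry: neighbour shells of the triangular lattice", {
  f <- orientation_field(0)
  # single layer: exactly 6 nearest neighbours at l_xy
  s1 <- lattice_spec("AAA", 0.4, rho_star = 10, n_stack = 1)
  cl <- build_lattice(s1, f, extent = 0.85)
  d <- sqrt(rowSums(cl$positions^2))[-1]
  expect_equal(sum(abs(d - 0.4) < 1e-9), 6)
  # shells at l_xy, sqrt(3) l_xy, 2 l_xy
  sh <- sort(unique(round(d, 9)))
  expect_equal(sh[1:3], 0.4 * c(1, sqrt(3), 2), tolerance = 1e-9)
})

test_that("close packing gives 12 nearest neighbours, 3 above and 3 below", {
  # ideal close packing: l_z = sqrt(2/3) l_xy, at interlayer distance l_xy
  l <- 0.5
  rho <- 2 / (sqrt(3) * l^2) / (sqrt(2 / 3) * l)
  f <- orientation_field(0)
  for (st in c("ABA", "ABC")) {
    s <- lattice_spec(st, l, rho)
    expect_equal(s$l_z_star, sqrt(2 / 3) * l, tolerance = 1e-12)
    cl <- build_lattice(s, f, extent = 1.4 * l)
    d <- sqrt(rowSums(cl$positions^2))[-1]
    nn <- abs(d - l) < 1e-9
    expect_equal(sum(nn), 12)
    z <- cl$positions[-1, 3][nn]
    expect_equal(sum(abs(z) < 1e-12), 6)   # in plane
    expect_equal(sum(z > 1e-12), 3)        # above
    expect_equal(sum(z < -1e-12), 3)       # below
  }
})

test_that("supercells reproduce the density exactly and wrap the twist", {
  s <- lattice_spec("ABC", 1 / 3, rho_star = 10)
  f <- orientation_field(30, theta1 = 120)
  cfg <- build_periodic_supercell(s, f, 2, 3, 6)
  expect_equal(nrow(cfg$positions) / prod(cfg$box), 10, tolerance = 1e-12)
  # orientations wrap seamlessly: layer n_z would equal layer 0
  expect_equal(drop(layer_orientation(6, f)), drop(layer_orientation(0, f)))
  # incommensurate cases are refused
  expect_error(build_periodic_supercell(s, f, 2, 2, 4), "period")
  expect_error(build_periodic_supercell(
    lattice_spec("ABA", 1 / 3, 10), orientation_field(0), 2, 2, 3), "period")
  # AAA with Theta1 = 120 needs n_z multiple of 3
  cfg3 <- build_periodic_supercell(lattice_spec("AAA", 0.6, 10),
                                   orientation_field(80, 120), 2, 2, 3)
  expect_equal(nrow(cfg3$positions) / prod(cfg3$box), 10, tolerance = 1e-12)
})

test_that("phi and 180 - phi give the same lattice energy", {
  p <- potential_params(kappa_star = 20, M = 3, n_trunc = 4)
  s <- lattice_spec("AAA", 0.6, 10)
  u1 <- energy_per_particle(s, orientation_field(70, 120), p)$u_total
  u2 <- energy_per_particle(s, orientation_field(110, 120), p)$u_total
  expect_equal(u1, u2, tolerance = 1e-10)
})

test_that("rod configurations validate their invariants", {
  expect_error(rod_configuration(matrix(0, 2, 3),
                                 matrix(c(1, 0, 0, 2, 0, 0), 2, 3,
                                        byrow = TRUE)), "unit")
  cfg <- rod_configuration(matrix(c(5, 0, 0), 1, 3),
                           matrix(c(0, 0, 1), 1, 3), box = c(2, 2, 2))
  expect_true(all(cfg$positions >= 0 & cfg$positions < 2))  # wrapped
})
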