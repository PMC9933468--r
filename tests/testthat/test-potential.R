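test_that("segment energy matches the far-field line-charge quadrature", {
  # the independent oracle pins the closed form: >= 100 randomised
  # well-separated pairs, relative error shrinking as r grows
  set.seed(42)
  for (kappa in c(5, 20)) {
    p <- potential_params(kappa_star = kappa, M = 15)
    err_near <- err_far <- numeric(0)
    for (i in 1:60) {
      vi <- drop(random_unit())
      vj <- drop(random_unit())
      rhat <- drop(random_unit())
      for (r in c(0.3, 1.2)) {  # both >> segment length 1/15
        u_pkg <- segment_pair_energy(r * rhat, vi, vj, p)
        u_orc <- quadrature_segment_energy(r * rhat, vi, vj, kappa, 15)
        rel <- abs(u_pkg - u_orc) / u_orc
        if (r < 1) err_near <- c(err_near, rel) else err_far <- c(err_far, rel)
      }
    }
    # the closed form is a far-field expansion: percent-level accuracy at
    # r ~ 5 segment lengths, sub-percent at r ~ 20, improving with r
    expect_lt(max(err_near), 0.05)
    expect_lt(max(err_far), 0.01)
    expect_lt(mean(err_far), mean(err_near))  # far field improves
  }
})

test_that("segment energy symmetries and decay", {
  p <- potential_params(kappa_star = 10, M = 5)
  set.seed(1)
  for (i in 1:20) {
    vi <- drop(random_unit()); vj <- drop(random_unit())
    r <- drop(random_unit()) * runif(1, 0.2, 2)
    u <- segment_pair_energy(r, vi, vj, p)
    expect_gt(u, 0)  # purely repulsive
    # pair exchange with negated separation
    expect_equal(segment_pair_energy(-r, vj, vi, p), u)
    # head-tail symmetry of either rod
    expect_equal(segment_pair_energy(r, -vi, vj, p), u)
    expect_equal(segment_pair_energy(r, vi, -vj, p), u)
  }
  # screened monotone decay at large r
  rhat <- c(0.6, 0.64, sqrt(1 - 0.6^2 - 0.64^2))
  us <- sapply(seq(1, 6, by = 0.5), function(r)
    segment_pair_energy(r * rhat, c(0, 0, 1), c(1, 0, 0), p))
  expect_true(all(diff(us) < 0))
  expect_lt(us[length(us)] / us[1], exp(-10 * 4))
})

test_that("segment energy input contracts are enforced", {
  p <- potential_params(kappa_star = 10)
  expect_error(segment_pair_energy(c(0, 0, 0), c(0, 0, 1), c(0, 0, 1), p),
               "positive")
  expect_error(segment_pair_energy(c(1, 0, 0), c(0, 0, 2), c(0, 0, 1), p),
               "unit")
  expect_error(potential_params(kappa_star = -1))
})

test_that("rod pair energy equals the naive double loop and its contracts", {
  p15 <- potential_params(kappa_star = 20, M = 15)
  # fixed reference case: parallel rods at separation 0.34
  u <- rod_pair_energy(c(0, 0, 0), c(0, 0, 1), c(0.34, 0, 0), c(0, 0, 1),
                       p15)
  expect_equal(u, naive_rod_pair(c(0, 0, 0), c(0, 0, 1), c(0.34, 0, 0),
                                 c(0, 0, 1), p15), tolerance = 1e-12)
  # randomised orientations, M = 7
  p7 <- potential_params(kappa_star = 12, M = 7)
  set.seed(3)
  for (i in 1:5) {
    vp <- drop(random_unit()); vq <- drop(random_unit())
    dq <- drop(random_unit()) * runif(1, 0.4, 1.5)
    expect_equal(rod_pair_energy(c(0, 0, 0), vp, dq, vq, p7),
                 naive_rod_pair(c(0, 0, 0), vp, dq, vq, p7),
                 tolerance = 1e-12)
    # translation invariance
    t0 <- c(0.3, -1, 2)
    expect_equal(rod_pair_energy(t0, vp, dq + t0, vq, p7),
                 rod_pair_energy(c(0, 0, 0), vp, dq, vq, p7))
  }
  # M = 1 degenerates to a single segment pair
  p1 <- potential_params(kappa_star = 12, M = 1)
  expect_equal(rod_pair_energy(c(0, 0, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2),
                               c(1, 0, 0), p1),
               segment_pair_energy(c(1, 1, 0) / sqrt(2), c(0, 0, 1),
                                   c(1, 0, 0), p1))
  expect_error(rod_pair_energy(c(1, 1, 1), c(0, 0, 1), c(1, 1, 1),
                               c(0, 0, 1), p1), "coincident")
})

test_that("energies scale exactly as Z^2 and linearly in lambda", {
  base <- potential_params(kappa_star = 15, M = 5)
  zc <- potential_params(kappa_star = 15, M = 5, Z = 3)
  lc <- potential_params(kappa_star = 15, M = 5, lambda_ref = 0.7)
  args <- list(c(0, 0, 0), c(0, 0, 1), c(0.5, 0.2, 0.4), c(1, 0, 0))
  u0 <- do.call(rod_pair_energy, c(args, list(base)))
  expect_equal(do.call(rod_pair_energy, c(args, list(zc))), 9 * u0)
  expect_equal(do.call(rod_pair_energy, c(args, list(lc))), 0.7 * u0)
})

test_that("truncation radii follow the cutoff rule", {
  p <- potential_params(kappa_star = 20, n_trunc = 10)
  r <- truncation_radii(p, rho_star = 10)
  expect_equal(r$segment_cutoff, 10 / 20 + 1.5 * 10^(-1 / 3))
  expect_equal(r$rod_cutoff, 1 + r$segment_cutoff)
  # worked values
  expect_equal(truncation_radii(potential_params(20, n_trunc = 10),
                                10)$segment_cutoff, 1.1962, tolerance = 1e-4)
  expect_equal(truncation_radii(potential_params(50, n_trunc = 10),
                                10)$segment_cutoff, 0.8962, tolerance = 1e-4)
  expect_error(truncation_radii(p, -1))
})
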