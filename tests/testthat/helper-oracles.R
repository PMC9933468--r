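# Independent oracles used across the suite.  All are deliberately naive:
# plain R loops and quadrature, sharing no code with the package kernels.

# Gauss-Legendre nodes/weights on [a, b]
gl_rule <- function(n, a, b) {
  if (requireNamespace("pracma", quietly = TRUE)) {
    g <- pracma::gaussLegendre(n, a, b)
    return(list(x = g$x, w = g$w))
  }
  # Golub-Welsch fallback
  i <- seq_len(n - 1)
  bet <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- bet
  J[cbind(i + 1, i)] <- bet
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# far-field oracle: the two segments as uniformly charged line segments of
# length 1/M, interacting via the point-Yukawa kernel, integrated by
# 24-point Gauss-Legendre quadrature per segment
quadrature_segment_energy <- function(r_ij, v_i, v_j, kappa, M,
                                      Z = 1, lambda = 1, n_nodes = 24) {
  ell <- 1 / M
  g <- gl_rule(n_nodes, -ell / 2, ell / 2)
  dens2 <- (Z / M / ell)^2      # line charge density squared
  u <- 0
  for (a in seq_along(g$x)) {
    p1 <- g$x[a] * v_i
    for (b in seq_along(g$x)) {
      d <- sqrt(sum((r_ij + g$x[b] * v_j - p1)^2))
      u <- u + g$w[a] * g$w[b] * exp(-kappa * d) / d
    }
  }
  lambda * dens2 * u
}

# naive double loop over all M x M segment pairs, using the package's
# segment energy only at the lowest level
naive_rod_pair <- function(pos_p, v_p, pos_q, v_q, params) {
  M <- params$M
  off <- ((1:M) - (M + 1) / 2) / M
  u <- 0
  for (k in 1:M) for (l in 1:M) {
    r <- (pos_q + off[l] * v_q) - (pos_p + off[k] * v_p)
    u <- u + segment_pair_energy(r, v_p, v_q, params)
  }
  u
}

# naive cluster sum: central rod (row 1) against every other rod
naive_central_energy <- function(config, params) {
  p <- config$positions
  v <- config$orientations
  u <- 0
  for (j in 2:nrow(p))
    u <- u + rod_pair_energy(p[1, ], v[1, ], p[j, ], v[j, ], params)
  u
}

# naive periodic total energy with explicit image loop (small boxes)
naive_total_energy_pbc <- function(config, params, n_img = 2) {
  p <- config$positions
  v <- config$orientations
  L <- config$box
  n <- nrow(p)
  rcut <- truncation_radii(params, n / prod(L))$rod_cutoff
  shifts <- as.matrix(expand.grid(x = -n_img:n_img, y = -n_img:n_img,
                                  z = -n_img:n_img))
  u <- 0
  for (i in 1:n) for (j in i:n) {
    d0 <- p[j, ] - p[i, ]
    for (s in seq_len(nrow(shifts))) {
      if (i == j && all(shifts[s, ] == 0)) next
      d <- d0 + shifts[s, ] * L
      if (sum(d^2) > rcut^2) next
      e <- rod_pair_energy(c(0, 0, 0), v[i, ], d, v[j, ], params)
      u <- u + if (i == j) e / 2 else e
    }
  }
  u
}

random_unit <- function(n = 1) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}
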