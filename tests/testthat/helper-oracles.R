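# Independent numerical oracles used across the suite. Everything here is
# written against the mathematical definitions, not against package
# internals.

# Richardson-extrapolated central difference of f along coordinate `dim`
richardson_diff <- function(f, x, dim, h = 1e-4) {
  step <- function(hh) {
    xp <- x; xp[dim] <- xp[dim] + hh
    xm <- x; xm[dim] <- xm[dim] - hh
    (f(xp) - f(xm)) / (2 * hh)
  }
  (4 * step(h / 2) - step(h)) / 3
}

# Damping kernels written directly from their defining formulas
oracle_kernel <- function(kind, k_i = NULL, k_j = NULL) {
  switch(kind,
    bare = function(r) 1 / r,
    f1 = function(r) (1 - exp(-k_i * r)) / r,
    f2 = function(r) {
      if (abs(k_i - k_j) < 1e-12) {
        (1 - (1 - k_i * r / 2) * exp(-k_i * r)) / r
      } else {
        (1 - k_i^2 / (k_i^2 - k_j^2) * exp(-k_i * r) -
           k_j^2 / (k_j^2 - k_i^2) * exp(-k_j * r)) / r
      }
    })
}

# --- point-charge cluster realization of a multipole site -------------------
# A site with net charge q, dipole mu and traceless quadrupole theta (3x3)
# is represented by point charges whose moments converge to (q, mu, theta)
# as delta -> 0; pairwise Coulomb sums then provide an independent
# electrostatic energy oracle.
multipole_cluster <- function(q, mu, theta, pos, delta) {
  charges <- q
  points <- matrix(pos, 1, 3)
  if (sqrt(sum(mu^2)) > 0) {
    u <- mu / sqrt(sum(mu^2))
    m <- sqrt(sum(mu^2)) / (2 * delta)
    charges <- c(charges, m, -m)
    points <- rbind(points, pos + delta * u, pos - delta * u)
  }
  # theta = (3/2) S_traceless with S the cluster second moment; realize
  # S = (2/3) theta through +/- charge pairs along its eigenvectors
  es <- eigen((2 / 3) * theta, symmetric = TRUE)
  for (m in 1:3) {
    lam <- es$values[m]
    if (abs(lam) < 1e-300) next
    v <- es$vectors[, m]
    qc <- lam / (2 * delta^2)
    charges <- c(charges, qc, qc, -2 * qc)
    points <- rbind(points, pos + delta * v, pos - delta * v, pos)
  }
  list(q = charges, x = points)
}

coulomb_sum <- function(ca, cb) {
  e <- 0
  for (i in seq_along(ca$q)) {
    d <- sweep(cb$x, 2, ca$x[i, ])
    e <- e + sum(ca$q[i] * cb$q / sqrt(rowSums(d^2)))
  }
  e
}

# Coulomb energy of two multipole sites via cluster discretization with
# two-level Richardson extrapolation in the cluster size (hartree)
oracle_multipole_energy <- function(qa, mua, tha, xa, qb, mub, thb, xb,
                                    delta = 0.08) {
  e_at <- function(dd) {
    coulomb_sum(multipole_cluster(qa, mua, tha, xa, dd),
                multipole_cluster(qb, mub, thb, xb, dd))
  }
  d1 <- e_at(delta); d2 <- e_at(delta / 2); d3 <- e_at(delta / 4)
  a1 <- (4 * d2 - d1) / 3
  a2 <- (4 * d3 - d2) / 3
  (16 * a2 - a1) / 15
}

# --- direct linear solve of the Thole polarization equations ----------------
# Re-coded from the model definition: isotropic alphas, exponential-cube
# damping, external field from the partner monomer's permanent multipoles.
oracle_induced_dipoles <- function(pos, alpha, q, mu, theta6, mono,
                                   a = 0.39) {
  n <- nrow(pos)
  lam <- function(u) {
    au3 <- a * u^3
    c(l3 = 1 - exp(-au3), l5 = 1 - (1 + au3) * exp(-au3),
      l7 = 1 - (1 + au3 + 0.6 * au3^2) * exp(-au3))
  }
  full_theta <- function(t6) {
    matrix(t6[c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
  }
  tmat <- matrix(0, 3 * n, 3 * n)
  f <- matrix(0, n, 3)
  for (i in 1:n) for (k in 1:n) {
    if (i == k) next
    d <- pos[i, ] - pos[k, ]
    r <- sqrt(sum(d^2))
    l <- lam(r / (alpha[i] * alpha[k])^(1 / 6))
    blk <- (l["l5"] * 3 * outer(d, d) / r^2 - l["l3"] * diag(3)) / r^3
    tmat[(3 * i - 2):(3 * i), (3 * k - 2):(3 * k)] <- blk
    if (mono[i] != mono[k]) {
      th <- full_theta(theta6[k, ])
      f[i, ] <- f[i, ] + l["l3"] * q[k] * d / r^3 + blk %*% mu[k, ] +
        5 * l["l7"] * sum(d * (th %*% d)) * d / r^7 -
        2 * l["l5"] * (th %*% d) / r^5
    }
  }
  amat <- diag(3 * n) - diag(rep(alpha, each = 3)) %*% tmat
  rhs <- rep(alpha, each = 3) * as.vector(t(f))
  matrix(solve(amat, rhs), n, 3, byrow = TRUE)
}
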