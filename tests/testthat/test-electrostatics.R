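test_that("charge-penetration damping has the right limits", {
  d0 <- elst_damping(3, 4, 1e-12)
  expect_equal(d0$f1_i, 0, tolerance = 1e-10)
  expect_equal(d0$f2, 0, tolerance = 1e-10)
  dinf <- elst_damping(3, 4, 100)
  expect_equal(dinf$f1_i, 1)
  expect_equal(dinf$f1_j, 1)
  expect_equal(dinf$f2, 1)
  expect_true(all(elst_damping(2, 3, seq(0.1, 5, 0.1))$f1_i > 0))
})

test_that("equal-exponent limit of the two-exponent damping matches a
           nearly-degenerate numerical evaluation", {
  f2_direct <- function(ki, kj, r) {
    1 - ki^2 / (ki^2 - kj^2) * exp(-ki * r) -
      kj^2 / (kj^2 - ki^2) * exp(-kj * r)
  }
  for (k in c(0.7, 2, 4.3)) {
    for (r in c(0.3, 1, 2.5, 6)) {
      lim <- elst_damping(k, k, r)$f2
      expect_equal(lim, 1 - (1 - k * r / 2) * exp(-k * r), tolerance = 1e-12)
      expect_lt(abs(lim - f2_direct(k, k * (1 + 1e-8), r)), 1e-6)
    }
  }
  # K_i = K_j = 2, r = 1: limit form gives exactly 1 - 0 * e^-2 = 1
  expect_equal(elst_damping(2, 2, 1)$f2, 1)
})

test_that("interaction tensors differentiate their kernels", {
  # derivative-chain oracle: each order is the Richardson central
  # difference of the analytic tensor one order below; rank 0 is checked
  # against an independently coded kernel formula
  withr::with_seed(42, {
    for (rep in 1:12) {
      kind <- sample(c("bare", "f1", "f2"), 1)
      ki <- runif(1, 0.5, 5)
      kj <- if (runif(1) < 0.2) ki else runif(1, 0.5, 5)
      rv <- rnorm(3) * runif(1, 0.8, 4)
      if (sqrt(sum(rv^2)) < 0.5) rv <- rv * 2
      tt <- interaction_tensors(rv, kind, k_i = ki, k_j = kj)
      kern <- oracle_kernel(kind, ki, kj)
      expect_equal(tt$t0, kern(sqrt(sum(rv^2))), tolerance = 1e-10)

      get_order <- function(x, n) {
        interaction_tensors(x, kind, k_i = ki, k_j = kj,
                            max_order = n)[[n + 1]]
      }
      for (n in 1:4) {
        lower <- function(x) get_order(x, n - 1)
        num <- vapply(1:3, function(dim) richardson_diff(lower, rv, dim),
                      if (n == 1) numeric(1) else lower(rv))
        scale <- max(abs(tt[[n + 1]]))
        expect_lt(max(abs(aperm_to_match(num, n) - tt[[n + 1]])),
                  1e-8 * scale)
      }
    }
  })
})

test_that("damped tensors approach bare tensors at large exponent", {
  rv <- c(1.1, -0.4, 0.7)
  bare <- interaction_tensors(rv, "bare")
  f1 <- interaction_tensors(rv, "f1", k_i = 400)
  f2 <- interaction_tensors(rv, "f2", k_i = 400, k_j = 500)
  for (nm in c("t0", "t1", "t2", "t3", "t4")) {
    expect_equal(f1[[nm]], bare[[nm]], tolerance = 1e-10)
    expect_equal(f2[[nm]], bare[[nm]], tolerance = 1e-10)
  }
})

test_that("two bare point charges obey Coulomb's law", {
  mk <- function(z, pos) {
    m <- sapt_monomer(tibble::tibble(element = "H", x = pos[1], y = pos[2],
                                     z = pos[3]), name = "q")
    m <- perceive_bonds(m)
    m$atoms$type <- "HC"
    m$properties <- tibble::tibble(
      Z = z, sigma = 1, mono_e = 0, dip_x = 0, dip_y = 0, dip_z = 0,
      qxx = 0, qxy = 0, qxz = 0, qyy = 0, qyz = 0, qzz = 0,
      h = 1, c6_free = 1, alpha_free = 1, r2 = 1, r4 = 1)
    m
  }
  for (r_ang in c(2, 3.7, 6)) {
    d <- sapt_dimer(mk(1, c(0, 0, 0)), mk(1, c(r_ang, 0, 0)))
    e <- electrostatic_energy(d, uniform_parameters())
    r_bohr <- r_ang / saptfit:::BOHR_ANGSTROM
    expect_equal(e, saptfit:::HARTREE_KCAL / r_bohr, tolerance = 1e-10)
  }
})

test_that("undamped multipole electrostatics matches the point-charge
           cluster oracle", {
  # large damping exponents put every f at 1 within machine precision, so
  # the model reduces to point-multipole electrostatics; the oracle builds
  # each site from point charges and Coulomb-sums them
  undamped <- uniform_parameters(kelst = 60)
  withr::with_seed(99, {
    for (rep in 1:12) {
      za <- sample(c(1, 6, 7, 8), 1); zb <- sample(c(1, 6, 7, 8), 1)
      qe_a <- -za + runif(1, -0.5, 0.5)
      qe_b <- -zb + runif(1, -0.5, 0.5)
      mua <- rnorm(3, 0, 0.4); mub <- rnorm(3, 0, 0.4)
      tha <- random_traceless(); thb <- random_traceless()
      sep <- runif(1, 3, 8)                       # bohr
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      xb <- sep * dir

      d <- two_site_dimer(za, qe_a, mua, tha, c(0, 0, 0),
                          zb, qe_b, mub, thb, xb)
      e_model <- electrostatic_energy(d, undamped) / saptfit:::HARTREE_KCAL
      e_oracle <- oracle_multipole_energy(
        za + qe_a, mua, tha, c(0, 0, 0), zb + qe_b, mub, thb, xb)
      expect_lt(abs(e_model - e_oracle), 1e-8 * max(abs(e_oracle), 0.1))
    }
  })
})

test_that("electrostatic energy is symmetric under monomer swap", {
  d <- fx_dimer()
  dsw <- d; dsw$a <- d$b; dsw$b <- d$a
  expect_equal(electrostatic_energy(dsw), electrostatic_energy(d),
               tolerance = 1e-12)
})
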