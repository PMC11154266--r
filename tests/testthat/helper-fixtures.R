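# Shared fixtures, built lazily and cached for the session. The benchmark
# fit is the expensive one; several tests reuse it.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fx_config <- function() fixture("config", function() synth_config(seed = 101))

fx_library <- function() {
  fixture("library", function() {
    lapply(builtin_monomer_library(), generate_properties,
           config = fx_config())
  })
}

fx_monomer <- function(name) {
  lib <- fx_library()
  lib[[match(name, vapply(lib, function(m) m$name, ""))]]
}

# one mid-sized dimer with properties, reused by energy tests
fx_dimer <- function() {
  fixture("dimer", function() {
    generate_dimer_configs(fx_monomer("formamide"), fx_monomer("methanol"),
                           1, fx_config())[[1]]
  })
}

fx_suite <- function() {
  fixture("suite", function() make_benchmark_suite(fx_config()))
}

# noiseless parameter-recovery fit on the synthetic benchmark
fx_fit <- function() {
  fixture("fit", function() {
    fit_global_parameters(fx_suite()$train, max_iter = 4000)
  })
}

# small random rotation matrix from an axis-angle draw
random_rotation_matrix <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

expect_components_equal <- function(a, b, tol) {
  for (cmp in c("elst", "exch", "indu", "disp", "total")) {
    expect_lt(abs(a[[cmp]] - b[[cmp]]), tol)
  }
}

# every interaction tensor is fully symmetric, so the index order of a
# numerically assembled derivative stack needs no permutation
aperm_to_match <- function(x, n) x

random_traceless <- function(scale = 0.5) {
  m <- matrix(rnorm(9, 0, scale), 3, 3)
  m <- (m + t(m)) / 2
  m - diag(3) * sum(diag(m)) / 3
}

# dimer of two single-atom monomers with fully specified multipoles
# (positions in bohr; theta as 3x3 traceless matrices)
two_site_dimer <- function(za, qe_a, mua, tha, xa, zb, qe_b, mub, thb, xb,
                           sigma = 1, alpha = 1) {
  site <- function(z, qe, mu, th, x, nm) {
    pos <- x * saptfit:::BOHR_ANGSTROM
    m <- sapt_monomer(tibble::tibble(element = "H", x = pos[1], y = pos[2],
                                     z = pos[3]), name = nm)
    m <- perceive_bonds(m)
    m$atoms$type <- "HC"
    m$properties <- tibble::tibble(
      Z = z, sigma = sigma, mono_e = min(qe, 0),
      dip_x = mu[1], dip_y = mu[2], dip_z = mu[3],
      qxx = th[1, 1], qxy = th[1, 2], qxz = th[1, 3],
      qyy = th[2, 2], qyz = th[2, 3], qzz = th[3, 3],
      h = 1, c6_free = 1, alpha_free = alpha, r2 = 1, r4 = 1)
    m
  }
  sapt_dimer(site(za, qe_a, mua, tha, xa, "site_a"),
             site(zb, qe_b, mub, thb, xb, "site_b"))
}
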