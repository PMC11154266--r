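#' Electrostatic damping functions
#'
#' Single- and two-exponent charge-penetration damping:
#' f1(K, r) = 1 - exp(-K r), and the two-exponent f2 built from both atoms'
#' exponents, switching to the series limit 1 - (1 - K r / 2) exp(-K r) when
#' the exponents agree to 1e-6 relative. Both tend to 1 at long range and to
#' 0 at contact.
#'
#' @param k_i,k_j Damping exponents, bohr^-1 (> 0); vectorized.
#' @param r Separation, bohr (> 0).
#' @return Tibble with columns `f1_i`, `f1_j`, `f2`.
#' @export
elst_damping <- function(k_i, k_j, r) {
  if (any(k_i <= 0) || any(k_j <= 0) || any(r <= 0)) {
    abort("damping needs positive exponents and separation",
          class = "saptfit_domain_error")
  }
  f2 <- r * eval_terms(f2_terms(k_i, k_j), r)  # terms encode f2(r)/r
  tibble::tibble(f1_i = 1 - exp(-k_i * r), f1_j = 1 - exp(-k_j * r), f2 = f2)
}

# quadratic-form helpers on packed symmetric 3x3 tensors (N x 6 storage,
# column order xx xy xz yy yz zz)
quad_rr <- function(th, v) {
  th[, 1] * v[, 1]^2 + th[, 4] * v[, 2]^2 + th[, 6] * v[, 3]^2 +
    2 * (th[, 2] * v[, 1] * v[, 2] + th[, 3] * v[, 1] * v[, 3] +
           th[, 5] * v[, 2] * v[, 3])
}

quad_vec <- function(th, v) {
  cbind(th[, 1] * v[, 1] + th[, 2] * v[, 2] + th[, 3] * v[, 3],
        th[, 2] * v[, 1] + th[, 4] * v[, 2] + th[, 5] * v[, 3],
        th[, 3] * v[, 1] + th[, 5] * v[, 2] + th[, 6] * v[, 3])
}

quad_ddot <- function(tha, thb) {
  tha[, 1] * thb[, 1] + tha[, 4] * thb[, 4] + tha[, 6] * thb[, 6] +
    2 * (tha[, 2] * thb[, 2] + tha[, 3] * thb[, 3] + tha[, 5] * thb[, 5])
}

# Damped multipole electrostatic energy per atom pair (hartree), vectorized
# over the pair table. Nuclear-nuclear is bare Coulomb; nucleus-multipole
# terms carry the single-exponent damping of the multipole-bearing atom;
# multipole-multipole terms carry the two-exponent damping. Contractions use
# the closed forms of the derivative tensors of the damped kernels.
elst_pair_energies <- function(pd, kelst) {
  ki <- kelst[pd$ti]
  kj <- kelst[pd$tj]
  r <- pd$r

  # nucleus-nucleus, bare kernel
  e <- pd$z_i * pd$z_j / r

  # multipoles of i against nucleus j: kernel f1(ki)/r, ranks 0-2
  cs <- radial_coeffs(kernel_terms("f1", ki = ki), r, 2)
  e <- e + pd$z_j * (pd$qe_i * cs[[1]] - cs[[2]] * pd$mu_i_r +
                       cs[[3]] * pd$ti_rr / 3)

  # nucleus i against multipoles of j: kernel f1(kj)/r
  cs <- radial_coeffs(kernel_terms("f1", ki = kj), r, 2)
  e <- e + pd$z_i * (pd$qe_j * cs[[1]] + cs[[2]] * pd$mu_j_r +
                       cs[[3]] * pd$tj_rr / 3)

  # multipoles of i against multipoles of j: kernel f2(ki,kj)/r, ranks 0-4
  cs <- radial_coeffs(f2_terms(ki, kj), r, 4)
  e + pd$qe_i * pd$qe_j * cs[[1]] +
    cs[[2]] * (pd$qe_i * pd$mu_j_r - pd$qe_j * pd$mu_i_r) -
    (cs[[3]] * pd$mu_i_r * pd$mu_j_r + cs[[2]] * pd$mu_dot) +
    cs[[3]] * (pd$qe_i * pd$tj_rr + pd$qe_j * pd$ti_rr) / 3 -
    (cs[[4]] * pd$mu_i_r * pd$tj_rr + 2 * cs[[3]] * pd$mi_tjr) / 3 +
    (cs[[4]] * pd$mu_j_r * pd$ti_rr + 2 * cs[[3]] * pd$mj_tir) / 3 +
    (cs[[5]] * pd$ti_rr * pd$tj_rr + 4 * cs[[4]] * pd$titj +
       2 * cs[[3]] * pd$th_ddot) / 9
}
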