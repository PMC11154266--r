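#' Combine atomic C6 coefficients into a pair coefficient
#'
#' Polarizability-weighted harmonic combination of two effective atomic C6
#' magnitudes:
#' c6_ij = 2 c6_i c6_j / \[(alpha_j/alpha_i) c6_i + (alpha_i/alpha_j) c6_j\].
#' Symmetric in (i, j); reduces to c for identical atoms.
#'
#' @param c6_i,c6_j Effective atomic C6 magnitudes, hartree bohr^6 (> 0).
#' @param alpha_i,alpha_j Effective polarizabilities, bohr^3 (> 0).
#' @return Pair C6 magnitude(s).
#' @export
combine_c6 <- function(c6_i, c6_j, alpha_i, alpha_j) {
  if (any(c(c6_i, c6_j, alpha_i, alpha_j) <= 0)) {
    abort("C6 combination needs positive inputs",
          class = "saptfit_domain_error")
  }
  2 * c6_i * c6_j / ((alpha_j / alpha_i) * c6_i + (alpha_i / alpha_j) * c6_j)
}

#' Scale free-atom dispersion data by the Hirshfeld ratio
#'
#' The in-molecule environment shrinks or swells an atom relative to its free
#' counterpart; the Hirshfeld volume ratio h rescales the free-atom values as
#' c6 = c6_free h^2 and alpha = alpha_free h.
#'
#' @param properties Per-atom property tibble (see [validate_properties()]).
#' @return Tibble with columns `c6_eff`, `alpha_eff`.
#' @export
scale_by_hirshfeld <- function(properties) {
  tibble::tibble(
    c6_eff = properties$c6_free * properties$h^2,
    alpha_eff = properties$alpha_free * properties$h
  )
}

#' Higher pair dispersion coefficients
#'
#' Builds C8 and C10 from the pair C6 using the radial-moment recursion:
#' Q_i = Z_i r4_i / r2_i, c8 = 3 c6 sqrt(Q_i Q_j), c10 = (49/40) c8^2 / c6.
#' The last relation holds exactly by construction.
#'
#' @param c6_ij Pair C6 magnitude(s).
#' @param z_i,z_j Nuclear charges.
#' @param r2_i,r4_i,r2_j,r4_j Radial expectation values (bohr^2, bohr^4).
#' @return Tibble with columns `c6`, `c8`, `c10`.
#' @export
higher_coefficients <- function(c6_ij, z_i, r2_i, r4_i, z_j, r2_j, r4_j) {
  q_i <- z_i * r4_i / r2_i
  q_j <- z_j * r4_j / r2_j
  c8 <- 3 * c6_ij * sqrt(q_i * q_j)
  tibble::tibble(c6 = c6_ij, c8 = c8, c10 = (49 / 40) * c8^2 / c6_ij)
}

#' Tang-Toennies damping function
#'
#' f_n(x) = 1 - exp(-x) sum_{k=0}^{n} x^k / k!, evaluated through the
#' regularized incomplete gamma function (numerically stable for large x).
#' Monotone increasing from f_n(0) = 0 to 1, with f_10 <= f_8 <= f_6.
#'
#' @param n Order (6, 8 or 10).
#' @param x Dimensionless damping argument (>= 0); vectorized.
#' @return Damping value(s) in \[0, 1).
#' @export
tang_toennies <- function(n, x) {
  stopifnot(n %in% c(6, 8, 10))
  if (any(x < 0)) {
    abort("Tang-Toennies argument must be non-negative",
          class = "saptfit_domain_error")
  }
  stats::pgamma(x, shape = n + 1)
}

# Damping argument from the pair overlap exponent, a smooth function of B and
# r that grows like B r at long range.
tt_argument <- function(b, r) {
  br <- b * r
  br + (2 * b^2 * r + 3 * b) * r / (br^2 + 3 * br + 3)
}
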