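#' Induction solver settings
#'
#' @param omega Mixing factor of the self-consistent iteration (0 < omega
#'   <= 1; default 0.7). The converged dipoles are independent of omega.
#' @param a_thole Thole smearing coefficient (default 0.39).
#' @param tol Convergence threshold: maximum per-atom induced-dipole change,
#'   a.u. (default 1e-10; the tight default keeps the induction energy
#'   reproducible to well below 1e-8 kcal/mol across equivalent frames).
#' @param max_iter Iteration cap (default 500).
#' @return List of class `sapt_induction_config`.
#' @export
induction_config <- function(omega = 0.7, a_thole = 0.39, tol = 1e-10,
                             max_iter = 500) {
  stopifnot(omega > 0, omega <= 1, tol > 0, max_iter >= 1)
  structure(list(omega = omega, a_thole = a_thole, tol = tol,
                 max_iter = max_iter),
            class = "sapt_induction_config")
}

# Thole exponential-cube damping factors for the field tensors
thole_lambdas <- function(u, a) {
  au3 <- a * u^3
  e <- exp(-au3)
  list(l3 = 1 - e, l5 = 1 - (1 + au3) * e,
       l7 = 1 - (1 + au3 + 0.6 * au3^2) * e)
}

# Permanent-multipole field (a.u.) of atom j evaluated at x (d = x - x_j),
# with Thole damping factors lam; q is the net charge Z + mono_e.
permanent_field <- function(d, q, mu, th, lam) {
  r2 <- sum(d^2); r <- sqrt(r2)
  thm <- matrix(th[c(1, 2, 3, 2, 4, 5, 3, 5, 6)], 3, 3)
  f <- lam$l3 * q * d / r^3
  f <- f + (lam$l5 * 3 * sum(mu * d) * d / r2 - lam$l3 * mu) / r^3
  td <- thm %*% d
  f + 5 * lam$l7 * sum(d * td) * d / r^7 - 2 * lam$l5 * td / r^5
}

# Damped dipole-field tensor block (3x3): field at i due to a dipole at k.
thole_dipole_block <- function(d, lam) {
  r2 <- sum(d^2); r <- sqrt(r2)
  (lam$l5 * 3 * outer(d, d) / r2 - lam$l3 * diag(3)) / r^3
}

#' Converged induced dipoles of a dimer
#'
#' Solves the Thole-damped induced-dipole equations by omega-mixed iteration:
#' each atom carries an isotropic polarizability (free-atom value scaled by
#' its Hirshfeld ratio); the external field is the permanent-multipole field
#' of the partner monomer; induced dipoles couple through damped dipole-field
#' tensors over all atom pairs. Iteration stops when the largest per-atom
#' dipole change falls below `config$tol`; failure to converge within
#' `config$max_iter` (the polarization catastrophe signature) is an error
#' reporting the last residual.
#'
#' @param dimer A [sapt_dimer()] whose monomers carry properties.
#' @param config An [induction_config()].
#' @return n x 3 matrix of induced dipoles (a.u.) with attributes `n_iter`,
#'   `f_ext` (external-field matrix) and `monomer` (1/2 ownership).
#' @export
induced_dipoles <- function(dimer, config = induction_config()) {
  at <- dimer_atoms(dimer)
  ind <- induced_dipoles_impl(at, config)
  if (!ind$converged) {
    abort(sprintf(
      "induction not converged after %d iterations (last residual %.3g a.u.)",
      config$max_iter, ind$residual), class = "saptfit_induction_error")
  }
  structure(ind$mu, n_iter = ind$n_iter, f_ext = ind$f_ext,
            monomer = at$mono)
}

induced_dipoles_impl <- function(at, config) {
  n <- nrow(at$pos)
  a <- config$a_thole
  alpha <- at$alpha_eff

  f_ext <- matrix(0, n, 3)
  tmat <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == i) next
      d <- at$pos[i, ] - at$pos[k, ]
      u <- sqrt(sum(d^2)) / (alpha[i] * alpha[k])^(1 / 6)
      lam <- thole_lambdas(u, a)
      if (at$mono[k] != at$mono[i]) {
        f_ext[i, ] <- f_ext[i, ] +
          permanent_field(d, at$q_net[k], at$mu_perm[k, ], at$th[k, ], lam)
      }
      tmat[(3 * i - 2):(3 * i), (3 * k - 2):(3 * k)] <-
        thole_dipole_block(d, lam)
    }
  }

  mu0 <- alpha * f_ext
  mu <- matrix(0, n, 3)
  vec <- function(m) as.vector(t(m))
  unvec <- function(v) matrix(v, n, 3, byrow = TRUE)
  converged <- FALSE
  residual <- Inf
  iter <- 0
  while (iter < config$max_iter) {
    iter <- iter + 1
    coupled <- unvec(tmat %*% vec(mu))
    mu_new <- (1 - config$omega) * mu +
      config$omega * (mu0 + alpha * coupled)
    residual <- max(abs(mu_new - mu))
    mu <- mu_new
    if (residual < config$tol) {
      converged <- TRUE
      break
    }
  }
  list(mu = mu, f_ext = f_ext, converged = converged, residual = residual,
       n_iter = iter)
}

# classical induction energy (hartree): induced dipoles of each monomer
# against the permanent field of the other, without a factor 1/2
induction_classical <- function(mu, f_ext) {
  -sum(mu * f_ext)
}
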