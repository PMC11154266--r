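# Damped Coulomb kernels and their Cartesian derivative tensors.
#
# Every electrostatic kernel used here has the form g(r)/r where g is 1 (bare
# Coulomb) or an exponential damping function. Such kernels are closed under
# differentiation in a small term algebra: each kernel is a sum of terms
# coef * r^q * exp(-k r), and the radial helper (1/r d/dr) maps the algebra to
# itself. Interaction tensors of rank n are then assembled exactly as
#   T^(n)_{a1..an} = sum_m c_{n-m} Sym[ delta^m (x) r^(n-2m) ]
# with c_m = ((1/r) d/dr)^m applied to the kernel -- the standard expansion of
# Cartesian derivatives of a radial function. Coefficients and exponents may
# be vectors so that one call evaluates all atom pairs at once.

# term set constructors ------------------------------------------------------

kernel_terms <- function(kind, ki = NULL, kj = NULL) {
  switch(
    kind,
    bare = list(list(coef = 1, q = -1L, k = 0, kid = "z")),
    f1 = {
      stopifnot(!is.null(ki))
      list(list(coef = 1, q = -1L, k = 0, kid = "z"),
           list(coef = -1, q = -1L, k = ki, kid = "i"))
    },
    f2 = f2_terms(ki, kj),
    abort(paste0("unknown kernel: ", kind))
  )
}

# The two-exponent damping has a removable singularity at equal exponents;
# below 1e-6 relative difference the series limit 1 - (1 - K r / 2) e^{-K r}
# is used. Vector-safe: the branch is selected per element.
f2_terms <- function(ki, kj) {
  stopifnot(!is.null(ki), !is.null(kj))
  n <- max(length(ki), length(kj))
  ki <- rep_len(ki, n); kj <- rep_len(kj, n)
  eq <- abs(ki - kj) < 1e-6 * ki
  den <- ki^2 - kj^2
  den[eq] <- 1
  ca <- ifelse(eq, -1, -ki^2 / den)   # coefficient of exp(-ki r)/r
  cb <- ifelse(eq, 0, kj^2 / den)     # coefficient of exp(-kj r)/r
  cc <- ifelse(eq, ki / 2, 0)         # coefficient of exp(-ki r) (limit form)
  list(list(coef = 1, q = -1L, k = 0, kid = "z"),
       list(coef = ca, q = -1L, k = ki, kid = "i"),
       list(coef = cb, q = -1L, k = kj, kid = "j"),
       list(coef = cc, q = 0L, k = ki, kid = "i"))
}

# (1/r d/dr) applied to a term set
radial_step <- function(terms) {
  out <- list()
  for (tm in terms) {
    if (tm$q != 0L) {
      out[[length(out) + 1]] <- list(coef = tm$coef * tm$q, q = tm$q - 2L,
                                     k = tm$k, kid = tm$kid)
    }
    out[[length(out) + 1]] <- list(coef = -tm$coef * tm$k, q = tm$q - 1L,
                                   k = tm$k, kid = tm$kid)
  }
  out
}

eval_terms <- function(terms, r) {
  total <- 0
  for (tm in terms) {
    total <- total + tm$coef * r^tm$q * exp(-tm$k * r)
  }
  total
}

# c_0 .. c_max for a kernel, each a vector parallel to r. The exponentials
# (at most one per distinct exponent) and the integer powers of r are
# evaluated once and shared across all derived terms.
radial_coeffs <- function(terms, r, max_order) {
  exps <- list(z = 1)
  for (tm in terms) {
    if (tm$kid != "z" && is.null(exps[[tm$kid]])) {
      exps[[tm$kid]] <- exp(-tm$k * r)
    }
  }
  rinv <- 1 / r
  qmin <- min(vapply(terms, function(tm) tm$q, 0L)) - 2L * max_order
  qmax <- max(vapply(terms, function(tm) tm$q, 0L))
  rpow <- vector("list", qmax - qmin + 1)
  pw <- r^qmax
  for (q in seq(qmax, qmin)) {
    rpow[[q - qmin + 1]] <- pw
    pw <- pw * rinv
  }
  eval_cached <- function(ts) {
    total <- 0
    for (tm in ts) {
      total <- total + tm$coef * rpow[[tm$q - qmin + 1]] * exps[[tm$kid]]
    }
    total
  }
  out <- vector("list", max_order + 1)
  out[[1]] <- eval_cached(terms)
  for (m in seq_len(max_order)) {
    terms <- radial_step(terms)
    out[[m + 1]] <- eval_cached(terms)
  }
  out
}

#' Damped multipole interaction tensors
#'
#' Successive Cartesian gradients (through 4th order) of a scalar kernel
#' g(r)/r, where g is 1 (`"bare"`), the single-exponent damping
#' f1 = 1 - exp(-k_i r) (`"f1"`), or the two-exponent damping f2 (`"f2"`).
#' Derivatives are taken with respect to the head of `r_vec` (the vector from
#' site i to site j), so rank-1 is the gradient at the j end.
#'
#' @param r_vec Length-3 separation vector, bohr.
#' @param kernel `"bare"`, `"f1"`, or `"f2"`.
#' @param k_i,k_j Damping exponents (bohr^-1); `k_i` for `"f1"`, both for
#'   `"f2"`.
#' @param max_order Highest tensor rank to build (0-4).
#' @return List `t0` (scalar), `t1` (3-vector), `t2` (3x3), `t3` (3x3x3),
#'   `t4` (3x3x3x3), up to `max_order`; each symmetric under index
#'   permutation.
#' @export
interaction_tensors <- function(r_vec, kernel = c("bare", "f1", "f2"),
                                k_i = NULL, k_j = NULL, max_order = 4) {
  kernel <- match.arg(kernel)
  stopifnot(length(r_vec) == 3, max_order >= 0, max_order <= 4)
  r <- sqrt(sum(r_vec^2))
  if (r <= 0) abort("zero separation", class = "saptfit_geometry_error")
  cs <- radial_coeffs(kernel_terms(kernel, k_i, k_j), r, max_order)
  out <- list(t0 = cs[[1]])
  if (max_order >= 1) out$t1 <- cs[[2]] * r_vec
  if (max_order >= 2) {
    out$t2 <- cs[[3]] * outer(r_vec, r_vec) + cs[[2]] * diag(3)
  }
  if (max_order >= 3) {
    t3 <- array(0, c(3, 3, 3))
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
      t3[a, b, cc] <- cs[[4]] * r_vec[a] * r_vec[b] * r_vec[cc] +
        cs[[3]] * (r_vec[a] * (b == cc) + r_vec[b] * (a == cc) +
                     r_vec[cc] * (a == b))
    }
    out$t3 <- t3
  }
  if (max_order >= 4) {
    t4 <- array(0, c(3, 3, 3, 3))
    rv <- r_vec
    for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (d in 1:3) {
      t4[a, b, cc, d] <-
        cs[[5]] * rv[a] * rv[b] * rv[cc] * rv[d] +
        cs[[4]] * (rv[a] * rv[b] * (cc == d) + rv[a] * rv[cc] * (b == d) +
                     rv[a] * rv[d] * (b == cc) + rv[b] * rv[cc] * (a == d) +
                     rv[b] * rv[d] * (a == cc) + rv[cc] * rv[d] * (a == b)) +
        cs[[3]] * ((a == b) * (cc == d) + (a == cc) * (b == d) +
                     (a == d) * (b == cc))
    }
    out$t4 <- t4
  }
  out
}
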