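# Flattened atomic data of a dimer in atomic units. Requires typed atoms and
# validated properties on both monomers; types are perceived on the fly when
# absent.
dimer_atoms <- function(dimer) {
  prep <- function(m) {
    if (any(is.na(m$atoms$type))) m <- assign_atom_types(m)
    if (is.null(m$properties)) {
      abort(sprintf("monomer '%s' has no atomic properties", m$name),
            class = "saptfit_properties_error")
    }
    m$properties <- validate_properties(m$properties)
    m
  }
  a <- prep(dimer$a); b <- prep(dimer$b)
  atoms <- dplyr::bind_rows(a$atoms, b$atoms)
  props <- dplyr::bind_rows(a$properties, b$properties)
  ti <- match(atoms$type, atom_type_labels())
  if (any(is.na(ti))) {
    abort("atom with unparameterized type", class = "saptfit_typing_error")
  }
  eff <- scale_by_hirshfeld(props)
  list(
    pos = as.matrix(atoms[, c("x", "y", "z")]) / BOHR_ANGSTROM,
    mono = rep(c(1L, 2L), c(nrow(a$atoms), nrow(b$atoms))),
    type_idx = ti,
    sigma = props$sigma,
    z = props$Z,
    qe = props$mono_e,
    q_net = props$Z + props$mono_e,
    mu_perm = as.matrix(props[, c("dip_x", "dip_y", "dip_z")]),
    th = as.matrix(props[, c("qxx", "qxy", "qxz", "qyy", "qyz", "qzz")]),
    alpha_eff = eff$alpha_eff,
    c6_eff = eff$c6_eff,
    r2 = props$r2,
    r4 = props$r4
  )
}

# All intermonomer atom pairs with the parameter-independent quantities the
# component models reuse: separation, overlap, multipoles, and damped
# dispersion terms.
pair_data <- function(at) {
  ia <- which(at$mono == 1L)
  ib <- which(at$mono == 2L)
  i <- rep(ia, times = length(ib))
  j <- rep(ib, each = length(ia))
  rvec <- at$pos[j, , drop = FALSE] - at$pos[i, , drop = FALSE]
  r <- sqrt(rowSums(rvec^2))
  b <- overlap_exponent(at$sigma[i], at$sigma[j])
  s <- overlap(at$sigma[i], at$sigma[j], r)
  c6 <- combine_c6(at$c6_eff[i], at$c6_eff[j],
                   at$alpha_eff[i], at$alpha_eff[j])
  cc <- higher_coefficients(c6, at$z[i], at$r2[i], at$r4[i],
                            at$z[j], at$r2[j], at$r4[j])
  x <- tt_argument(b, r)
  mu_i <- at$mu_perm[i, , drop = FALSE]
  mu_j <- at$mu_perm[j, , drop = FALSE]
  th_i <- at$th[i, , drop = FALSE]
  th_j <- at$th[j, , drop = FALSE]
  ti_r <- quad_vec(th_i, rvec)
  tj_r <- quad_vec(th_j, rvec)
  list(
    ti = at$type_idx[i], tj = at$type_idx[j],
    r = r, rvec = rvec, s = s,
    z_i = at$z[i], z_j = at$z[j],
    qe_i = at$qe[i], qe_j = at$qe[j],
    mu_i = mu_i, mu_j = mu_j, th_i = th_i, th_j = th_j,
    # parameter-independent multipole contractions reused per evaluation
    mu_i_r = rowSums(mu_i * rvec), mu_j_r = rowSums(mu_j * rvec),
    mu_dot = rowSums(mu_i * mu_j),
    ti_rr = quad_rr(th_i, rvec), tj_rr = quad_rr(th_j, rvec),
    mi_tjr = rowSums(mu_i * tj_r), mj_tir = rowSums(mu_j * ti_r),
    titj = rowSums(ti_r * tj_r), th_ddot = quad_ddot(th_i, th_j),
    d6 = cc$c6 * tang_toennies(6, x) / r^6,
    d810 = cc$c8 * tang_toennies(8, x) / r^8 +
      cc$c10 * tang_toennies(10, x) / r^10
  )
}

# subset every per-pair field of a pair table (used for type-restricted
# gradient evaluations)
subset_pairs <- function(pd, mask) {
  lapply(pd, function(f) {
    if (is.matrix(f)) f[mask, , drop = FALSE] else f[mask]
  })
}

# 9x9 matrix accumulating v over type pairs: M[ti, tj] = sum of v
type_pair_matrix <- function(ti, tj, v) {
  m <- matrix(0, 9, 9)
  idx <- ti + 9L * (tj - 1L)
  acc <- rowsum(v, idx)
  m[as.integer(rownames(acc))] <- acc
  m
}

# Parameter-independent compilation of one dimer; the expensive pieces
# (pair table, induced dipoles) are computed once and reused across
# parameter sets during fitting.
compile_dimer <- function(dimer, config = induction_config()) {
  at <- dimer_atoms(dimer)
  pd <- pair_data(at)
  ind <- induced_dipoles_impl(at, config)
  if (!ind$converged) {
    abort(sprintf(
      "induction not converged for '%s' (last residual %.3g a.u.)",
      dimer$name, ind$residual), class = "saptfit_induction_error")
  }
  list(
    pd = pd,
    w_overlap = type_pair_matrix(pd$ti, pd$tj, pd$s),
    w_disp = type_pair_matrix(pd$ti, pd$tj, pd$d810),
    disp_const = sum(pd$d6),
    e_ind_classical = HARTREE_KCAL * induction_classical(ind$mu, ind$f_ext),
    reference = dimer$reference,
    name = dimer$name,
    n_atoms = nrow(at$pos)
  )
}

bilinear <- function(w, k) as.numeric(crossprod(k, w %*% k))

components_from_compiled <- function(comp, pv) {
  elst <- HARTREE_KCAL * sum(elst_pair_energies(comp$pd, pv$kelst))
  exch <- bilinear(comp$w_overlap, pv$kexch)
  indu <- comp$e_ind_classical + bilinear(comp$w_overlap, pv$kindu)
  disp <- -HARTREE_KCAL * (comp$disp_const + bilinear(comp$w_disp, pv$kdisp))
  tibble::tibble(elst = elst, exch = exch, indu = indu, disp = disp,
                 total = elst + exch + indu + disp)
}

#' Component energies of a dimer
#'
#' Evaluates the four component models for a dimer whose monomers carry atom
#' types and atomic properties: damped multipole electrostatics, density-
#' overlap exchange, Thole-iterated induction plus its overlap correction,
#' and Tang-Toennies damped dispersion. All values in kcal/mol; the `total`
#' column is their sum by construction.
#'
#' @param dimer A [sapt_dimer()] with properties on both monomers.
#' @param params Global parameter tibble (see [default_parameters()]).
#' @param config An [induction_config()].
#' @return One-row tibble with columns `elst`, `exch`, `indu`, `disp`,
#'   `total`.
#' @export
sapt_energy <- function(dimer, params = default_parameters(),
                        config = induction_config()) {
  comp <- compile_dimer(dimer, config)
  components_from_compiled(comp, param_vectors(params))
}

#' @rdname sapt_energy
#' @export
exchange_energy <- function(dimer, params = default_parameters()) {
  pv <- param_vectors(params)
  pd <- pair_data(dimer_atoms(dimer))
  bilinear(type_pair_matrix(pd$ti, pd$tj, pd$s), pv$kexch)
}

#' @rdname sapt_energy
#' @export
electrostatic_energy <- function(dimer, params = default_parameters()) {
  pv <- param_vectors(params)
  pd <- pair_data(dimer_atoms(dimer))
  HARTREE_KCAL * sum(elst_pair_energies(pd, pv$kelst))
}

#' @rdname sapt_energy
#' @export
dispersion_energy <- function(dimer, params = default_parameters()) {
  pv <- param_vectors(params)
  pd <- pair_data(dimer_atoms(dimer))
  -HARTREE_KCAL *
    (sum(pd$d6) + bilinear(type_pair_matrix(pd$ti, pd$tj, pd$d810), pv$kdisp))
}

#' @rdname sapt_energy
#' @export
induction_energy <- function(dimer, params = default_parameters(),
                             config = induction_config()) {
  pv <- param_vectors(params)
  at <- dimer_atoms(dimer)
  pd <- pair_data(at)
  ind <- induced_dipoles_impl(at, config)
  if (!ind$converged) {
    abort(sprintf("induction not converged (last residual %.3g a.u.)",
                  ind$residual), class = "saptfit_induction_error")
  }
  HARTREE_KCAL * induction_classical(ind$mu, ind$f_ext) +
    bilinear(type_pair_matrix(pd$ti, pd$tj, pd$s), pv$kindu)
}

#' Predict component energies for a dataset
#'
#' @param manifest Dataset tibble with a `dimer` list-column (see
#'   [make_benchmark_suite()] or [read_manifest()]).
#' @param params Global parameter tibble.
#' @param config An [induction_config()].
#' @return Tibble with one row per dimer: `name`, `elst`, `exch`, `indu`,
#'   `disp`, `total` (kcal/mol).
#' @export
predict_sapt <- function(manifest, params = default_parameters(),
                         config = induction_config()) {
  rows <- purrr::map2(manifest$dimer, manifest$name, function(d, nm) {
    dplyr::bind_cols(tibble::tibble(name = nm), sapt_energy(d, params, config))
  })
  dplyr::bind_rows(rows)
}

#' Reference component energies of a dataset
#'
#' @param manifest Dataset tibble with a `dimer` list-column whose dimers
#'   carry reference components.
#' @return Tibble with one row per dimer: `name` plus the five energy fields.
#' @export
reference_components <- function(manifest) {
  rows <- purrr::map2(manifest$dimer, manifest$name, function(d, nm) {
    if (is.null(d$reference)) {
      abort(sprintf("dimer '%s' has no reference components", nm),
            class = "saptfit_reference_error")
    }
    dplyr::bind_cols(tibble::tibble(name = nm), d$reference)
  })
  dplyr::bind_rows(rows)
}
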