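PROP_COLS <- c("Z", "sigma", "mono_e", "dip_x", "dip_y", "dip_z",
               "qxx", "qxy", "qxz", "qyy", "qyz", "qzz",
               "h", "c6_free", "alpha_free", "r2", "r4")

#' Validate a per-atom property table
#'
#' Checks the invariants of the atomic-property record: positive valence
#' width, non-positive electronic monopole, traceless quadrupole (|trace| <
#' 1e-10), positive Hirshfeld ratio, free-atom C6, polarizability and radial
#' moments.
#'
#' @param properties Tibble with columns `Z`, `sigma`, `mono_e`,
#'   `dip_x/y/z`, `qxx..qzz`, `h`, `c6_free`, `alpha_free`, `r2`, `r4`
#'   (atomic units, global Cartesian frame).
#' @return The validated tibble, invisibly usable in pipelines.
#' @export
validate_properties <- function(properties) {
  properties <- tibble::as_tibble(properties)
  missing <- setdiff(PROP_COLS, names(properties))
  if (length(missing) > 0) {
    abort(paste0("property table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "saptfit_properties_error")
  }
  with(properties, {
    if (any(sigma <= 0)) {
      abort("non-positive valence width", class = "saptfit_properties_error")
    }
    if (any(mono_e > 0)) {
      abort("electronic monopole must be <= 0",
            class = "saptfit_properties_error")
    }
    tr <- qxx + qyy + qzz
    if (any(abs(tr) > 1e-10)) {
      abort(sprintf("quadrupole trace %.3g exceeds 1e-10", max(abs(tr))),
            class = "saptfit_properties_error")
    }
    if (any(h <= 0) || any(c6_free <= 0) || any(alpha_free <= 0) ||
        any(r2 <= 0) || any(r4 <= 0)) {
      abort("h, c6_free, alpha_free, r2, r4 must all be positive",
            class = "saptfit_properties_error")
    }
  })
  properties
}

#' Read a per-atom property sidecar
#'
#' Structured key-value (YAML) sidecar in atomic units and the global frame,
#' atom order matching the geometry file. All property invariants are
#' validated on load.
#'
#' @param path File path.
#' @param n_atoms Optional expected atom count (error on mismatch).
#' @return Validated property tibble.
#' @export
read_properties <- function(path, n_atoms = NULL) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$atoms)) {
    abort(sprintf("%s: no 'atoms' list", path),
          class = "saptfit_properties_error")
  }
  rows <- lapply(doc$atoms, function(a) {
    tibble::tibble(
      Z = as.numeric(a$Z), sigma = as.numeric(a$sigma),
      mono_e = as.numeric(a$mono_e),
      dip_x = a$dipole[1], dip_y = a$dipole[2], dip_z = a$dipole[3],
      qxx = a$quadrupole[1], qxy = a$quadrupole[2], qxz = a$quadrupole[3],
      qyy = a$quadrupole[4], qyz = a$quadrupole[5], qzz = a$quadrupole[6],
      h = as.numeric(a$h), c6_free = as.numeric(a$c6_free),
      alpha_free = as.numeric(a$alpha_free),
      r2 = as.numeric(a$r2), r4 = as.numeric(a$r4)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(n_atoms) && nrow(out) != n_atoms) {
    abort(sprintf("%s: %d property records for %d atoms", path, nrow(out),
                  n_atoms), class = "saptfit_properties_error")
  }
  validate_properties(out)
}

#' Write a per-atom property sidecar
#'
#' @param properties Validated property tibble.
#' @param path Output path.
#' @param name Monomer identifier stored in the document.
#' @return `path`, invisibly.
#' @export
write_properties <- function(properties, path, name = "monomer") {
  properties <- validate_properties(properties)
  atoms <- lapply(seq_len(nrow(properties)), function(i) {
    p <- properties[i, ]
    list(Z = p$Z, sigma = p$sigma, mono_e = p$mono_e,
         dipole = c(p$dip_x, p$dip_y, p$dip_z),
         quadrupole = c(p$qxx, p$qxy, p$qxz, p$qyy, p$qyz, p$qzz),
         h = p$h, c6_free = p$c6_free, alpha_free = p$alpha_free,
         r2 = p$r2, r4 = p$r4)
  })
  yaml::write_yaml(list(name = name, atoms = atoms), path,
                   precision = 15)
  invisible(path)
}
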