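#' Construct a monomer
#'
#' A monomer bundles an atom table (element and position in angstrom), an
#' optional bond list, an optional per-atom property table, a name, and a
#' functional-group class tag. Bonds may be supplied explicitly (e.g. from a
#' dataset manifest); otherwise call [perceive_bonds()].
#'
#' @param atoms Tibble or data frame with columns `element`, `x`, `y`, `z`
#'   (angstrom) and optionally `type`.
#' @param name Identifier.
#' @param group_class One of the eight functional-group classes
#'   (`"alkane"`, `"alkene"`, `"alkyne"`, `"alcohol"`, `"aldehyde"`,
#'   `"ketone"`, `"carboxylic_acid"`, `"amide"`) or `"other"`.
#' @param bonds Two-column integer matrix of bonded atom index pairs, or NULL.
#' @param properties Per-atom property tibble (see [read_properties()]), or
#'   NULL.
#' @return An object of class `sapt_monomer`.
#' @export
sapt_monomer <- function(atoms, name = "monomer", group_class = "other",
                         bonds = NULL, properties = NULL) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  bad <- setdiff(unique(atoms$element), ELEMENTS)
  if (length(bad) > 0) {
    abort(paste0("unsupported element(s): ", paste(bad, collapse = ", ")),
          class = "saptfit_element_error")
  }
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos))) {
    abort("non-finite atomic coordinates", class = "saptfit_geometry_error")
  }
  if (!"type" %in% names(atoms)) atoms$type <- NA_character_
  if (!is.null(properties)) {
    properties <- tibble::as_tibble(properties)
    if (nrow(properties) != nrow(atoms)) {
      abort("property table length does not match atom count",
            class = "saptfit_properties_error")
    }
  }
  structure(
    list(name = name, group_class = group_class, atoms = atoms,
         bonds = bonds, properties = properties),
    class = "sapt_monomer"
  )
}

#' @export
print.sapt_monomer <- function(x, ...) {
  cat("<sapt_monomer> ", x$name, " (", x$group_class, "), ",
      nrow(x$atoms), " atoms\n", sep = "")
  print(x$atoms)
  invisible(x)
}

monomer_positions <- function(monomer) {
  as.matrix(monomer$atoms[, c("x", "y", "z")])
}

#' Perceive bonds from interatomic distances
#'
#' A pair of atoms is bonded when their distance is below `scale` times the
#' sum of their covalent radii. Intended as the fallback when connectivity is
#' not supplied explicitly.
#'
#' @param monomer A [sapt_monomer()].
#' @param scale Multiplier on the covalent-radius sum (default 1.2).
#' @return The monomer with its `bonds` field set (two-column index matrix,
#'   i < j).
#' @export
perceive_bonds <- function(monomer, scale = 1.2) {
  pos <- monomer_positions(monomer)
  n <- nrow(pos)
  if (n == 1) {
    monomer$bonds <- matrix(integer(0), ncol = 2)
    return(monomer)
  }
  rcov <- COVALENT_RADII[monomer$atoms$element]
  d <- as.matrix(stats::dist(pos))
  if (any(d[upper.tri(d)] < 0.3)) {
    abort("overlapping atoms (interatomic distance < 0.3 angstrom)",
          class = "saptfit_geometry_error")
  }
  cut <- outer(rcov, rcov, "+") * scale
  bonded <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  bonds <- matrix(as.integer(bonded), ncol = 2,
                  dimnames = NULL)[order(bonded[, 1], bonded[, 2]), ,
                                   drop = FALSE]
  lone <- setdiff(seq_len(n), unique(as.vector(bonds)))
  if (length(lone) > 0 && n > 1) {
    warn(paste0("atom(s) without bonds in multi-atom monomer '",
                monomer$name, "': ", paste(lone, collapse = ", ")))
  }
  monomer$bonds <- bonds
  monomer
}

#' Assign atom types
#'
#' Types every atom from its element and connectivity: hydrogen by the element
#' of its bonding partner (`HC`/`HN`/`HO`), carbon by neighbor count
#' (`C4`/`C3`/`C2`), nitrogen with three neighbors (`N3`), oxygen with one or
#' two neighbors (`O1`/`O2`). Any element/coordination combination outside the
#' enumeration is an error naming the atom.
#'
#' @param monomer A [sapt_monomer()] with bonds perceived or supplied.
#' @return The monomer with `atoms$type` filled.
#' @export
assign_atom_types <- function(monomer) {
  if (is.null(monomer$bonds)) monomer <- perceive_bonds(monomer)
  el <- monomer$atoms$element
  n <- length(el)
  nb <- vector("list", n)
  if (nrow(monomer$bonds) > 0) {
    for (r in seq_len(nrow(monomer$bonds))) {
      i <- monomer$bonds[r, 1]; j <- monomer$bonds[r, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  type <- character(n)
  for (i in seq_len(n)) {
    deg <- length(nb[[i]])
    type[i] <- switch(
      el[i],
      H = {
        if (deg != 1) type_error(monomer, i, "H must have exactly one bond")
        paste0("H", el[nb[[i]][1]])
      },
      C = {
        if (!deg %in% c(2, 3, 4)) {
          type_error(monomer, i, "C must have 2, 3 or 4 neighbors")
        }
        paste0("C", deg)
      },
      N = {
        if (deg != 3) type_error(monomer, i, "N must have 3 neighbors")
        "N3"
      },
      O = {
        if (!deg %in% c(1, 2)) {
          type_error(monomer, i, "O must have 1 or 2 neighbors")
        }
        paste0("O", deg)
      }
    )
    if (el[i] == "H" && !type[i] %in% c("HC", "HN", "HO")) {
      type_error(monomer, i, "H bonded to unsupported partner")
    }
  }
  monomer$atoms$type <- type
  monomer
}

type_error <- function(monomer, i, msg) {
  abort(sprintf("cannot type atom %d (%s) of '%s': %s",
                i, monomer$atoms$element[i], monomer$name, msg),
        class = "saptfit_typing_error")
}

#' Construct a dimer
#'
#' Two monomers sharing one global coordinate frame, with an optional
#' reference record of SAPT component energies.
#'
#' @param monomer_a,monomer_b [sapt_monomer()] objects.
#' @param name Identifier.
#' @param reference Optional named numeric with entries `elst`, `exch`,
#'   `indu`, `disp` (kcal/mol); `total` is derived as their sum.
#' @return An object of class `sapt_dimer`.
#' @export
sapt_dimer <- function(monomer_a, monomer_b, name = NULL, reference = NULL) {
  if (is.null(name)) name <- paste(monomer_a$name, monomer_b$name, sep = "-")
  pa <- monomer_positions(monomer_a)
  pb <- monomer_positions(monomer_b)
  dmin <- min(cross_distances(pa, pb))
  if (!is.finite(dmin) || dmin <= 0) {
    abort("monomers overlap: minimum interatomic distance must be > 0",
          class = "saptfit_geometry_error")
  }
  if (!is.null(reference)) reference <- as_components(reference)
  structure(list(name = name, a = monomer_a, b = monomer_b,
                 reference = reference),
            class = "sapt_dimer")
}

#' @export
print.sapt_dimer <- function(x, ...) {
  cat("<sapt_dimer> ", x$name, ": ", nrow(x$a$atoms), " + ",
      nrow(x$b$atoms), " atoms\n", sep = "")
  if (!is.null(x$reference)) {
    cat("reference components (kcal/mol):\n")
    print(x$reference)
  }
  invisible(x)
}

cross_distances <- function(pa, pb) {
  na <- nrow(pa); nb <- nrow(pb)
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-")
  dz <- outer(pa[, 3], pb[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

# Canonical one-row component record; enforces total = sum of components.
as_components <- function(x) {
  x <- as.list(x)
  need <- c("elst", "exch", "indu", "disp")
  if (!all(need %in% names(x))) {
    abort("component record needs elst, exch, indu, disp",
          class = "saptfit_components_error")
  }
  out <- tibble::tibble(elst = as.numeric(x$elst), exch = as.numeric(x$exch),
                        indu = as.numeric(x$indu), disp = as.numeric(x$disp))
  out$total <- out$elst + out$exch + out$indu + out$disp
  if (!is.null(x$total) && abs(out$total - as.numeric(x$total)) > 1e-9) {
    abort("stored total differs from component sum by more than 1e-9 kcal/mol",
          class = "saptfit_components_error")
  }
  out
}

#' Rigidly transform a dimer
#'
#' Applies a rotation followed by a translation to both monomers, co-rotating
#' dipoles and quadrupoles so the transformation is covariant. Used for frame
#' invariance checks and scan geometry manipulation.
#'
#' @param dimer A [sapt_dimer()].
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation Length-3 shift, angstrom (default zero).
#' @return The transformed dimer.
#' @export
transform_dimer <- function(dimer, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  dimer$a <- transform_monomer(dimer$a, rotation, translation)
  dimer$b <- transform_monomer(dimer$b, rotation, translation)
  dimer
}

transform_monomer <- function(monomer, rotation, translation) {
  pos <- monomer_positions(monomer) %*% t(rotation)
  pos <- sweep(pos, 2, -translation)
  monomer$atoms$x <- pos[, 1]
  monomer$atoms$y <- pos[, 2]
  monomer$atoms$z <- pos[, 3]
  if (!is.null(monomer$properties)) {
    pr <- monomer$properties
    mu <- as.matrix(pr[, c("dip_x", "dip_y", "dip_z")]) %*% t(rotation)
    pr$dip_x <- mu[, 1]; pr$dip_y <- mu[, 2]; pr$dip_z <- mu[, 3]
    for (i in seq_len(nrow(pr))) {
      q <- quad_matrix(pr[i, ])
      q <- rotation %*% q %*% t(rotation)
      pr$qxx[i] <- q[1, 1]; pr$qxy[i] <- q[1, 2]; pr$qxz[i] <- q[1, 3]
      pr$qyy[i] <- q[2, 2]; pr$qyz[i] <- q[2, 3]; pr$qzz[i] <- q[3, 3]
    }
    monomer$properties <- pr
  }
  monomer
}

quad_matrix <- function(row) {
  matrix(c(row$qxx, row$qxy, row$qxz,
           row$qxy, row$qyy, row$qyz,
           row$qxz, row$qyz, row$qzz), 3, 3)
}

#' Center of mass of a monomer
#'
#' @param monomer A [sapt_monomer()].
#' @return Length-3 numeric, angstrom.
#' @export
center_of_mass <- function(monomer) {
  m <- ATOMIC_MASS[monomer$atoms$element]
  pos <- monomer_positions(monomer)
  colSums(pos * m) / sum(m)
}
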