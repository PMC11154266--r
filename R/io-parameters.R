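#' Reference global-parameter tables
#'
#' Two atom-typed global parameter sets for the four component models:
#' `"base"`, fitted against homodimer training data, and `"augmented"`,
#' refitted after heterodimer augmentation of the training set. `kelst` is an
#' inverse length (bohr^-1) entering the electrostatic damping, `kexch` and
#' `kindu` scale the dimensionless density overlap (kcal/mol), and `kdisp` is
#' the dimensionless weight of the higher dispersion terms.
#'
#' @param set `"base"` or `"augmented"`.
#' @return Tibble with columns `type`, `kelst`, `kexch`, `kindu`, `kdisp`.
#' @export
default_parameters <- function(set = c("base", "augmented")) {
  set <- match.arg(set)
  if (set == "base") {
    tab <- tibble::tribble(
      ~type, ~kelst, ~kexch, ~kindu, ~kdisp,
      "HC", 3.644, 0.982, 0.144, 0.003,
      "HN", 2.903, 0.978, 0.678, 0.046,
      "HO", 2.683, 0.741, 0.734, 0.018,
      "C4", 3.229, 2.261, 0.676, 0.214,
      "C3", 3.336, 2.476, 1.616, 0.377,
      "C2", 3.119, 2.589, 0.938, 0.667,
      "N3", 3.358, 4.333, 1.877, 0.079,
      "O1", 3.885, 4.676, 1.530, 0.660,
      "O2", 4.752, 5.405, 1.025, 0.107
    )
  } else {
    tab <- tibble::tribble(
      ~type, ~kelst, ~kexch, ~kindu, ~kdisp,
      "HC", 4.750, 1.061, 0.003, 0.162,
      "HN", 2.647, 0.965, 0.444, 0.153,
      "HO", 2.632, 0.905, 0.427, 0.059,
      "C4", 2.999, 2.065, 0.787, 0.060,
      "C3", 3.323, 2.979, 1.265, 0.740,
      "C2", 3.162, 2.575, 1.186, 0.674,
      "N3", 4.111, 6.546, 0.924, 0.019,
      "O1", 3.977, 4.016, 2.598, 0.158,
      "O2", 5.115, 4.656, 1.509, 0.057
    )
  }
  validate_parameters(tab)
}

#' Uniform parameter table
#'
#' Convenience initializer: every atom type gets the same value for each
#' component (default 1 in its native units), the standard starting point for
#' fitting.
#'
#' @param kelst,kexch,kindu,kdisp Fill values.
#' @return Parameter tibble.
#' @export
uniform_parameters <- function(kelst = 1, kexch = 1, kindu = 1, kdisp = 1) {
  validate_parameters(tibble::tibble(
    type = atom_type_labels(),
    kelst = kelst, kexch = kexch, kindu = kindu, kdisp = kdisp
  ))
}

#' Validate a global-parameter table
#'
#' @param params Tibble with columns `type`, `kelst`, `kexch`, `kindu`,
#'   `kdisp`; one row per atom type, all values positive.
#' @return The table, rows ordered as [atom_type_labels()].
#' @export
validate_parameters <- function(params) {
  params <- tibble::as_tibble(params)
  need <- c("type", "kelst", "kexch", "kindu", "kdisp")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    abort(paste0("parameter table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "saptfit_parameters_error")
  }
  labels <- atom_type_labels()
  if (!setequal(params$type, labels) || nrow(params) != length(labels)) {
    abort("parameter table must have exactly one row per atom type",
          class = "saptfit_parameters_error")
  }
  vals <- as.matrix(params[, c("kelst", "kexch", "kindu", "kdisp")])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all global parameters must be positive and finite",
          class = "saptfit_parameters_error")
  }
  params[match(labels, params$type), need]
}

#' Read / write a global-parameter table
#'
#' Tab-delimited text with a header row and one row per atom type
#' (`type kelst kexch kindu kdisp`). Writing uses a full-precision decimal
#' representation so that `read_parameters(write_parameters(p))` reproduces
#' `p` exactly.
#'
#' @param path File path.
#' @return For `read_parameters`, the validated parameter tibble.
#' @export
read_parameters <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_parameters(tab)
}

#' @rdname read_parameters
#' @param params Parameter tibble.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  out <- data.frame(
    type = params$type,
    kelst = sprintf("%.17g", params$kelst),
    kexch = sprintf("%.17g", params$kexch),
    kindu = sprintf("%.17g", params$kindu),
    kdisp = sprintf("%.17g", params$kdisp)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# params tibble -> named component vectors indexed by type label
param_vectors <- function(params) {
  params <- validate_parameters(params)
  lapply(stats::setNames(c("kelst", "kexch", "kindu", "kdisp"),
                         c("kelst", "kexch", "kindu", "kdisp")),
         function(col) stats::setNames(params[[col]], params$type))
}
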