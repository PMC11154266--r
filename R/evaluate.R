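#' Error report (MAE / RMSE per component)
#'
#' Mean absolute error and root mean square error between predicted and
#' reference component energies, per component and for the total. Inputs are
#' matched by row order and must have equal length.
#'
#' @param predictions,references Tibbles with columns `elst`, `exch`,
#'   `indu`, `disp`, `total` (e.g. from [predict_sapt()] and
#'   [reference_components()]).
#' @return Tibble with columns `component`, `mae`, `rmse`, `n` (kcal/mol).
#' @export
error_report <- function(predictions, references) {
  if (nrow(predictions) != nrow(references)) {
    abort("prediction and reference tables differ in length",
          class = "saptfit_evaluation_error")
  }
  comps <- c(COMPONENTS, "total")
  rows <- purrr::map(comps, function(cmp) {
    d <- predictions[[cmp]] - references[[cmp]]
    tibble::tibble(component = cmp, mae = mean(abs(d)),
                   rmse = sqrt(mean(d^2)), n = length(d))
  })
  dplyr::bind_rows(rows)
}

#' Long-format correlation table
#'
#' One row per dimer per energy field, pairing reference with predicted
#' values and carrying the hydrogen-bond class flag, ready for correlation
#' plotting.
#'
#' @param predictions,references Component tibbles matched by row order,
#'   each with a `name` column.
#' @param hb_flags Logical vector: is the dimer hydrogen-bond capable
#'   (any monomer from the carboxylic-acid / amide / alcohol donor classes)?
#' @return Tibble with columns `name`, `component`, `reference`,
#'   `predicted`, `hbond`.
#' @export
correlation_table <- function(predictions, references, hb_flags) {
  if (nrow(predictions) != nrow(references) ||
      nrow(predictions) != length(hb_flags)) {
    abort("predictions, references and flags differ in length",
          class = "saptfit_evaluation_error")
  }
  comps <- c(COMPONENTS, "total")
  rows <- purrr::map(comps, function(cmp) {
    tibble::tibble(name = predictions$name, component = cmp,
                   reference = references[[cmp]],
                   predicted = predictions[[cmp]], hbond = hb_flags)
  })
  dplyr::bind_rows(rows)
}

#' Correlation plot of predicted vs reference energies
#'
#' @param cor_table Output of [correlation_table()].
#' @return A ggplot: predicted against reference, faceted by component,
#'   hydrogen-bonded dimers highlighted.
#' @export
plot_correlation <- function(cor_table) {
  ggplot2::ggplot(cor_table,
                  ggplot2::aes(x = .data$reference, y = .data$predicted,
                               colour = .data$hbond)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~component, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#3366aa",
                                            `TRUE` = "#cc3333"),
                                 name = "H-bonded") +
    ggplot2::labs(x = "reference energy (kcal/mol)",
                  y = "predicted energy (kcal/mol)")
}

# functional-group classes treated as hydrogen-bond donors
HB_CLASSES <- c("carboxylic_acid", "amide", "alcohol")

#' Hydrogen-bond class of a dimer
#'
#' A dimer is flagged hydrogen-bond capable when either monomer belongs to a
#' donor class (carboxylic acid, amide, alcohol). Assigned from the
#' functional-group tags, not detected geometrically.
#'
#' @param dimer A [sapt_dimer()].
#' @return Logical scalar.
#' @export
is_hbonded <- function(dimer) {
  any(c(dimer$a$group_class, dimer$b$group_class) %in% HB_CLASSES)
}

#' Center-of-mass potential-energy scan
#'
#' Rigidly translates monomer B along the line joining the monomer centers
#' of mass so that the center-of-mass distance equals `factor` times its
#' input value, and evaluates the component energies at every grid point.
#' When `ref_params` is supplied a reference curve is evaluated alongside and
#' separations are normalized to the reference curve's equilibrium distance.
#' The equilibrium of each curve is the grid minimum refined by a quadratic
#' fit through the three bracketing points.
#'
#' @param dimer A [sapt_dimer()] with properties.
#' @param params Parameter table for the predicted curve.
#' @param grid Increasing positive scale factors of the current
#'   center-of-mass distance.
#' @param ref_params Optional parameter table for the reference curve.
#' @param config An [induction_config()].
#' @return Object of class `sapt_scan`: a tibble with one row per grid point
#'   (`factor`, `separation` in bohr, `flagged` for points with interatomic
#'   contacts under 0.5 bohr, the five predicted energy fields, reference
#'   fields when requested, and `sep_norm`), with equilibrium estimates in
#'   attributes `equilibrium` and `ref_equilibrium` (bohr).
#' @export
com_scan <- function(dimer, params = default_parameters(),
                     grid = seq(0.8, 2.0, by = 0.05), ref_params = NULL,
                     config = induction_config()) {
  stopifnot(all(grid > 0), !is.unsorted(grid, strictly = TRUE))
  com_a <- center_of_mass(dimer$a)
  com_b <- center_of_mass(dimer$b)
  d0 <- sqrt(sum((com_b - com_a)^2))
  axis <- (com_b - com_a) / d0

  rows <- purrr::map(grid, function(f) {
    d <- dimer
    d$b <- transform_monomer(d$b, diag(3), (f - 1) * d0 * axis)
    dmin <- min(cross_distances(monomer_positions(d$a),
                                monomer_positions(d$b))) / BOHR_ANGSTROM
    out <- tibble::tibble(factor = f,
                          separation = f * d0 / BOHR_ANGSTROM,
                          flagged = dmin < 0.5)
    out <- dplyr::bind_cols(out, sapt_energy(d, params, config))
    if (!is.null(ref_params)) {
      ref <- sapt_energy(d, ref_params, config)
      names(ref) <- paste0("ref_", names(ref))
      out <- dplyr::bind_cols(out, ref)
    }
    out
  })
  tab <- dplyr::bind_rows(rows)

  eq <- refine_minimum(tab$separation, tab$total)
  ref_eq <- if (is.null(ref_params)) NA_real_ else {
    refine_minimum(tab$separation, tab$ref_total)
  }
  tab$sep_norm <- tab$separation / (if (is.na(ref_eq)) eq else ref_eq)
  structure(tab, equilibrium = eq, ref_equilibrium = ref_eq,
            class = c("sapt_scan", class(tab)))
}

# grid minimum refined by the quadratic through the three bracketing points
refine_minimum <- function(x, y) {
  i <- which.min(y)
  if (i == 1 || i == length(y)) {
    warn("energy minimum at scan boundary; equilibrium not bracketed")
    return(x[i])
  }
  x1 <- x[i - 1]; x2 <- x[i]; x3 <- x[i + 1]
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  num <- (x2 - x1)^2 * (y2 - y3) - (x2 - x3)^2 * (y2 - y1)
  den <- (x2 - x1) * (y2 - y3) - (x2 - x3) * (y2 - y1)
  if (den == 0) return(x2)
  x2 - 0.5 * num / den
}

#' @export
autoplot.sapt_scan <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    tab, dplyr::any_of(c("total", "ref_total")),
    names_to = "curve", values_to = "energy")
  long$curve <- ifelse(long$curve == "total", "predicted", "reference")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sep_norm, y = .data$energy,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "normalized center-of-mass separation",
                  y = "total energy (kcal/mol)", colour = NULL)
}
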