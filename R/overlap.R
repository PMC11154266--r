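#' Density overlap between two atoms
#'
#' Dimensionless overlap of two Slater-like valence densities with widths
#' `sigma_i`, `sigma_j` (bohr) at separation `r` (bohr):
#' S = \[(1/3)(Br)^2 + Br + 1\] exp(-Br) with overlap exponent
#' B = (sigma_i sigma_j)^(-1/2). S is 1 at contact and strictly decreasing in
#' r. All arguments vectorize.
#'
#' @param sigma_i,sigma_j Valence widths, bohr (> 0).
#' @param r Separation, bohr (> 0).
#' @return Overlap value(s) in (0, 1].
#' @export
overlap <- function(sigma_i, sigma_j, r) {
  if (any(sigma_i <= 0) || any(sigma_j <= 0)) {
    abort("valence widths must be positive", class = "saptfit_domain_error")
  }
  if (any(r <= 0)) {
    abort("separation must be positive", class = "saptfit_domain_error")
  }
  br <- overlap_exponent(sigma_i, sigma_j) * r
  (br^2 / 3 + br + 1) * exp(-br)
}

# B_ij = (sigma_i sigma_j)^(-1/2), bohr^-1
overlap_exponent <- function(sigma_i, sigma_j) {
  1 / sqrt(sigma_i * sigma_j)
}
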