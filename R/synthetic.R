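# --- idealized geometry builders -------------------------------------------

unitv <- function(v) v / sqrt(sum(v^2))

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)
}

# three tetrahedral hydrogens on a carbon whose single heavy bond points
# along `axis` (unit vector from the carbon toward its heavy neighbor)
methyl_h <- function(c_pos, axis, r_ch = 1.09, phase = 0) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unitv(pracma_cross(axis, ref))
  v <- pracma_cross(axis, u)
  ct <- -1 / 3                       # cos(109.471 deg)
  st <- sqrt(1 - ct^2)
  t(vapply(0:2, function(k) {
    phi <- phase + 2 * pi * k / 3
    c_pos + r_ch * (ct * axis + st * (cos(phi) * u + sin(phi) * v))
  }, numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

build_monomer <- function(name, group_class, elements, coords) {
  m <- sapt_monomer(
    tibble::tibble(element = elements, x = coords[, 1], y = coords[, 2],
                   z = coords[, 3]),
    name = name, group_class = group_class)
  assign_atom_types(m)
}

geom_methane <- function() {
  s <- 1.09 / sqrt(3)
  build_monomer("methane", "alkane", c("C", rep("H", 4)), rbind(
    c(0, 0, 0), c(s, s, s), c(s, -s, -s), c(-s, s, -s), c(-s, -s, s)))
}

geom_ethane <- function() {
  c1 <- c(0, 0, 0.77); c2 <- c(0, 0, -0.77)
  build_monomer("ethane", "alkane", c("C", "C", rep("H", 6)), rbind(
    c1, c2,
    methyl_h(c1, c(0, 0, -1), phase = 0),
    methyl_h(c2, c(0, 0, 1), phase = pi / 3)))
}

geom_ethene <- function() {
  a <- 121.5 * pi / 180
  c1 <- c(-0.665, 0, 0); c2 <- c(0.665, 0, 0)
  h <- 1.08
  build_monomer("ethene", "alkene", c("C", "C", rep("H", 4)), rbind(
    c1, c2,
    c1 + h * c(cos(a), sin(a), 0), c1 + h * c(cos(a), -sin(a), 0),
    c2 + h * c(-cos(a), sin(a), 0), c2 + h * c(-cos(a), -sin(a), 0)))
}

geom_ethyne <- function() {
  build_monomer("ethyne", "alkyne", c("C", "C", "H", "H"), rbind(
    c(-0.60, 0, 0), c(0.60, 0, 0), c(-1.66, 0, 0), c(1.66, 0, 0)))
}

geom_methanol <- function() {
  a <- 108.5 * pi / 180
  cpos <- c(0, 0, 0); o <- c(1.43, 0, 0)
  ho <- o + 0.96 * c(-cos(a), 0, sin(a))
  build_monomer("methanol", "alcohol", c("C", "O", "H", rep("H", 3)), rbind(
    cpos, o, ho, methyl_h(cpos, c(1, 0, 0), phase = pi / 6)))
}

geom_formaldehyde <- function() {
  a <- 121.8 * pi / 180
  build_monomer("formaldehyde", "aldehyde", c("C", "O", "H", "H"), rbind(
    c(0, 0, 0), c(1.21, 0, 0),
    1.10 * c(cos(a), sin(a), 0), 1.10 * c(cos(a), -sin(a), 0)))
}

geom_acetone <- function() {
  half <- 58.25 * pi / 180               # half the C-C-C angle
  cc <- c(0, 0, 0); o <- c(0, 1.22, 0)
  d1 <- c(sin(half), -cos(half), 0); d2 <- c(-sin(half), -cos(half), 0)
  cm1 <- 1.52 * d1; cm2 <- 1.52 * d2
  build_monomer("acetone", "ketone",
                c("C", "O", "C", "C", rep("H", 6)), rbind(
    cc, o, cm1, cm2,
    methyl_h(cm1, -d1, phase = 0), methyl_h(cm2, -d2, phase = pi)))
}

geom_formic_acid <- function() {
  cpos <- c(0, 0, 0)
  o1 <- c(0, 1.21, 0)                       # carbonyl
  a <- 125 * pi / 180
  d2 <- c(sin(a), cos(a), 0)
  o2 <- 1.36 * d2                           # hydroxyl oxygen
  hc <- -1.10 * unitv(c(0, 1, 0) + d2)
  w <- unitv(cpos - o2)
  ho <- o2 + 0.97 * as.vector(rot_z(-106 * pi / 180) %*% w)
  build_monomer("formic_acid", "carboxylic_acid",
                c("C", "O", "O", "H", "H"), rbind(cpos, o1, o2, hc, ho))
}

geom_formamide <- function() {
  cpos <- c(0, 0, 0)
  o <- c(0, 1.22, 0)
  a <- 125 * pi / 180
  dn <- c(sin(a), cos(a), 0)
  n <- 1.36 * dn
  hc <- -1.10 * unitv(c(0, 1, 0) + dn)
  w <- unitv(cpos - n)
  h1 <- n + 1.01 * as.vector(rot_z(120 * pi / 180) %*% w)
  h2 <- n + 1.01 * as.vector(rot_z(-120 * pi / 180) %*% w)
  build_monomer("formamide", "amide",
                c("C", "O", "N", "H", "H", "H"), rbind(cpos, o, n, hc, h1, h2))
}

#' Built-in monomer library
#'
#' Nine idealized textbook monomers spanning the eight organic
#' functional-group classes (alkane, alkene, alkyne, alcohol, aldehyde,
#' ketone, carboxylic acid, amide) whose atom types jointly cover the full
#' nine-label enumeration. Geometries are ideal internal coordinates, not
#' optimized structures.
#'
#' @return List of typed [sapt_monomer()] objects.
#' @export
builtin_monomer_library <- function() {
  list(geom_methane(), geom_ethane(), geom_ethene(), geom_ethyne(),
       geom_methanol(), geom_formaldehyde(), geom_acetone(),
       geom_formic_acid(), geom_formamide())
}

# --- synthetic configuration ------------------------------------------------

#' Synthetic benchmark configuration
#'
#' Fixes every random draw of the generator. The ground-truth parameter set
#' defaults to the base reference table; references are produced by the
#' implemented energy models under those parameters (model-consistent) with
#' optional per-component Gaussian noise.
#'
#' @param seed Integer master seed; all downstream draws derive from it.
#' @param n_train_replicates Homodimer configurations per library monomer.
#' @param n_test_per_pair Heterodimer configurations per monomer pair.
#' @param separation_range Center-of-mass separation range as factors of the
#'   contact distance (sum of monomer radii).
#' @param noise_sigma Per-component Gaussian noise, kcal/mol (>= 0).
#' @param ground_truth Hidden ground-truth parameter table.
#' @param property_jitter Relative log-normal perturbation of the free-atom
#'   base properties.
#' @return List of class `sapt_synth_config`.
#' @export
synth_config <- function(seed = 1, n_train_replicates = 6,
                         n_test_per_pair = 1,
                         separation_range = c(0.4, 1.2),
                         noise_sigma = 0,
                         ground_truth = default_parameters("base"),
                         property_jitter = 0.05) {
  stopifnot(noise_sigma >= 0, length(separation_range) == 2,
            all(separation_range > 0), property_jitter >= 0)
  structure(list(seed = as.integer(seed),
                 n_train_replicates = n_train_replicates,
                 n_test_per_pair = n_test_per_pair,
                 separation_range = separation_range,
                 noise_sigma = noise_sigma,
                 ground_truth = validate_parameters(ground_truth),
                 property_jitter = property_jitter),
            class = "sapt_synth_config")
}

# stable small sub-seed derived from the master seed and a string tag
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Generate plausible atomic properties for a monomer
#'
#' Element-wise free-atom base values (valence width, polarizability, C6,
#' radial moments, Hirshfeld ratio) with seeded multiplicative jitter;
#' atom-type-based partial charges renormalized so electronic monopoles sum
#' to minus the electron count; small seeded dipoles and traceless
#' quadrupoles in the global frame. Deterministic for a fixed seed.
#'
#' @param monomer Typed [sapt_monomer()].
#' @param config A [synth_config()].
#' @return The monomer with its `properties` table filled.
#' @export
generate_properties <- function(monomer, config = synth_config()) {
  if (any(is.na(monomer$atoms$type))) monomer <- assign_atom_types(monomer)
  el <- monomer$atoms$element
  ty <- monomer$atoms$type
  n <- length(el)
  base <- FREE_ATOM[match(el, FREE_ATOM$element), ]
  j <- config$property_jitter
  props <- withr::with_seed(sub_seed(config$seed, monomer$name), {
    jit <- function(x, scale = j) x * exp(stats::rnorm(n, 0, scale))
    q <- TYPE_CHARGE[ty] + stats::rnorm(n, 0, 0.02)
    q <- q - mean(q)                      # neutral monomer
    dip <- matrix(stats::rnorm(3 * n, 0, 0.05), n, 3)
    quad <- t(vapply(seq_len(n), function(i) {
      m <- matrix(stats::rnorm(9, 0, 0.1), 3, 3)
      m <- (m + t(m)) / 2
      m <- m - diag(3) * sum(diag(m)) / 3
      c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
    }, numeric(6)))
    tibble::tibble(
      Z = ATOMIC_NUMBER[el],
      sigma = jit(SYNTH_SIGMA[el]),
      mono_e = -ATOMIC_NUMBER[el] + q,
      dip_x = dip[, 1], dip_y = dip[, 2], dip_z = dip[, 3],
      qxx = quad[, 1], qxy = quad[, 2], qxz = quad[, 3],
      qyy = quad[, 4], qyz = quad[, 5], qzz = quad[, 6],
      h = jit(base$hirshfeld, j / 2),
      c6_free = jit(base$c6_free),
      alpha_free = jit(base$alpha_free),
      r2 = jit(base$r2),
      r4 = jit(base$r4)
    )
  })
  monomer$properties <- validate_properties(props)
  monomer
}

# Valence-density decay lengths (bohr) used by the generator. Chosen so that
# density overlaps at van der Waals contact are of order 1e-2 to 1e-1, which
# puts exchange energies at the few-kcal/mol scale typical of equilibrium
# dimers under order-unity global parameters.
SYNTH_SIGMA <- c(H = 1.10, C = 1.50, N = 1.40, O = 1.30)

monomer_radius <- function(monomer) {
  pos <- monomer_positions(monomer)
  com <- center_of_mass(monomer)
  max(sqrt(rowSums(sweep(pos, 2, com)^2))) + 1.7   # vdW margin, angstrom
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate random dimer configurations
#'
#' Centers monomer A at the origin, applies a seeded random rigid rotation
#' to each monomer, and places monomer B along a random direction at a
#' center-of-mass distance drawn from `config$separation_range` times the
#' contact distance (sum of monomer radii). The separation factors are
#' stratified: configuration i of n draws from the i-th equal sub-interval
#' of the range, so every monomer pair is guaranteed both compressed-wall
#' and stretched configurations regardless of the seed. Configurations with
#' any interatomic distance under 2 bohr are rejected and redrawn (up to
#' 1000 attempts each).
#'
#' @param monomer_a,monomer_b Typed monomers with properties.
#' @param n Number of configurations.
#' @param config A [synth_config()].
#' @return List of `n` [sapt_dimer()] objects named
#'   `<a>-<b>-<index>`.
#' @export
generate_dimer_configs <- function(monomer_a, monomer_b, n,
                                   config = synth_config()) {
  if (n == 0) return(list())
  contact <- monomer_radius(monomer_a) + monomer_radius(monomer_b)
  tag <- paste(monomer_a$name, monomer_b$name, sep = "-")
  lo <- config$separation_range[1]
  width <- (config$separation_range[2] - lo) / n
  withr::with_seed(sub_seed(config$seed, tag), {
    purrr::map(seq_len(n), function(i) {
      for (attempt in seq_len(1000)) {
        a <- transform_monomer(monomer_a, random_rotation(),
                               -center_of_mass(monomer_a))
        a <- transform_monomer(a, diag(3), -center_of_mass(a))
        b <- transform_monomer(monomer_b, random_rotation(),
                               -center_of_mass(monomer_b))
        b <- transform_monomer(b, diag(3), -center_of_mass(b))
        e <- stats::rnorm(3)
        e <- e / sqrt(sum(e^2))
        d <- stats::runif(1, lo + (i - 1) * width, lo + i * width) * contact
        b <- transform_monomer(b, diag(3), d * e)
        dmin <- min(cross_distances(monomer_positions(a),
                                    monomer_positions(b)))
        if (dmin / BOHR_ANGSTROM >= 2.0) {
          return(sapt_dimer(a, b, name = paste0(tag, "-", i)))
        }
      }
      abort(sprintf("could not place dimer %s within 1000 attempts", tag),
            class = "saptfit_synth_error")
    })
  })
}

#' Attach model-consistent reference energies
#'
#' Evaluates each component with the hidden ground-truth parameters and adds
#' independent seeded Gaussian noise of `config$noise_sigma` per component;
#' the stored total is the sum of the four (noisy) components, preserving
#' the component-sum invariant. With zero noise the references are exactly
#' recoverable by [sapt_energy()] under the ground-truth parameters.
#'
#' @param dimers List of [sapt_dimer()] objects with properties.
#' @param config A [synth_config()].
#' @param induction An [induction_config()].
#' @return The list with each dimer's `reference` filled.
#' @export
generate_reference_energies <- function(dimers, config = synth_config(),
                                        induction = induction_config()) {
  purrr::imap(dimers, function(d, i) {
    comps <- sapt_energy(d, config$ground_truth, induction)
    noisy <- withr::with_seed(sub_seed(config$seed, paste0("noise-", d$name)), {
      comps[COMPONENTS] + stats::rnorm(4, 0, config$noise_sigma)
    })
    d$reference <- as_components(noisy)
    d
  })
}

GROUP_SUPER <- c(alkane = "AaAeAy", alkene = "AaAeAy", alkyne = "AaAeAy",
                 alcohol = "AcAdK", aldehyde = "AcAdK", ketone = "AcAdK",
                 carboxylic_acid = "CAA", amide = "CAA")

dimer_manifest_row <- function(dimer) {
  tibble::tibble(
    name = dimer$name,
    group_a = dimer$a$group_class,
    group_b = dimer$b$group_class,
    subgroup = paste(sort(unique(GROUP_SUPER[c(dimer$a$group_class,
                                               dimer$b$group_class)])),
                     collapse = "-"),
    hbond = is_hbonded(dimer),
    natoms = nrow(dimer$a$atoms) + nrow(dimer$b$atoms),
    dimer = list(dimer)
  )
}

#' Build a dataset manifest from dimers
#'
#' Assembles a list of dimers into the tabular dataset form used by the
#' trainer and evaluator: one row per dimer with functional-group tags,
#' supergroup label, hydrogen-bond flag, atom count, and the dimer itself
#' in a list-column.
#'
#' @param dimers List of [sapt_dimer()] objects.
#' @return Dataset tibble.
#' @export
as_manifest <- function(dimers) {
  dplyr::bind_rows(purrr::map(dimers, dimer_manifest_row))
}

#' Generate the synthetic train/test benchmark
#'
#' Builds the full synthetic study: the nine library monomers receive seeded
#' atomic properties; the training set holds homodimer configurations of
#' each monomer, the test set heterodimer configurations of every monomer
#' pair; all dimers carry model-consistent reference component energies
#' under the hidden ground-truth parameters (plus optional noise). When
#' `dir` is given the two manifests, geometries, property sidecars,
#' reference energies and the ground-truth table are written beneath it.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory.
#' @param induction An [induction_config()].
#' @return List with `train` and `test` manifest tibbles (columns `name`,
#'   `group_a`, `group_b`, `subgroup`, `hbond`, `natoms`, `dimer`).
#' @export
make_benchmark_suite <- function(config = synth_config(), dir = NULL,
                                 induction = induction_config()) {
  lib <- purrr::map(builtin_monomer_library(), generate_properties,
                    config = config)
  train_dimers <- purrr::map(lib, function(m) {
    generate_dimer_configs(m, m, config$n_train_replicates, config)
  })
  pairs <- utils::combn(length(lib), 2)
  test_dimers <- purrr::map(seq_len(ncol(pairs)), function(k) {
    generate_dimer_configs(lib[[pairs[1, k]]], lib[[pairs[2, k]]],
                           config$n_test_per_pair, config)
  })
  train <- as_manifest(generate_reference_energies(
    purrr::flatten(train_dimers), config, induction))
  test <- as_manifest(generate_reference_energies(
    purrr::flatten(test_dimers), config, induction))
  if (!is.null(dir)) {
    write_manifest(train, file.path(dir, "train"), name = "train")
    write_manifest(test, file.path(dir, "test"), name = "test")
    write_parameters(config$ground_truth, file.path(dir, "ground_truth.tsv"))
  }
  list(train = train, test = test)
}
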